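# synthetic Lorentz-oscillator material (NOT a measured polymer)
# columns: wavelength_um  eta  kappa
2.500000 1.39919910 0.00001738
2.634921 1.39909027 0.00002131
2.769841 1.39897018 0.00002603
2.904762 1.39883749 0.00003171
3.039683 1.39869057 0.00003855
3.174603 1.39852748 0.00004683
3.309524 1.39834583 0.00005689
3.444444 1.39814273 0.00006919
3.579365 1.39791456 0.00008433
3.714286 1.39765679 0.00010314
3.849206 1.39736365 0.00012675
3.984127 1.39702767 0.00015676
4.119048 1.39663899 0.00019545
4.253968 1.39618437 0.00024622
4.388889 1.39564552 0.00031427
4.523810 1.39499652 0.00040783
4.658730 1.39419937 0.00054060
4.793651 1.39319613 0.00073656
4.928571 1.39189414 0.00104073
5.063492 1.39013675 0.00154519
5.198413 1.38764117 0.00246086
5.333333 1.38386399 0.00435099
5.468254 1.37779363 0.00907129
5.603175 1.36966440 0.02429060
5.738095 1.39267024 0.05944172
5.873016 1.42881004 0.03157645
6.007937 1.42294747 0.01248950
6.142857 1.41684705 0.00641538
6.277778 1.41289108 0.00396740
6.412698 1.41020188 0.00277508
6.547619 1.40823229 0.00212230
6.682540 1.40668725 0.00174234
6.817460 1.40539824 0.00152028
6.952381 1.40426022 0.00140247
7.087302 1.40320060 0.00136433
7.222222 1.40216259 0.00139803
7.357143 1.40109494 0.00150859
7.492063 1.39994401 0.00171504
7.626984 1.39864587 0.00205692
7.761905 1.39711672 0.00261016
7.896825 1.39524122 0.00352357
8.031746 1.39286635 0.00510658
8.166667 1.38985538 0.00805123
8.301587 1.38652990 0.01396785
8.436508 1.38614177 0.02577760
8.571429 1.39973974 0.03948322
8.706349 1.42019900 0.03340860
8.841270 1.42503885 0.01963030
8.976190 1.42298766 0.01155504
9.111111 1.42025288 0.00741072
9.246032 1.41797712 0.00514273
9.380952 1.41620070 0.00379446
9.515873 1.41481151 0.00293374
9.650794 1.41370690 0.00235174
9.785714 1.41281173 0.00193956
9.920635 1.41207319 0.00163649
10.055556 1.41145405 0.00140667
10.190476 1.41092770 0.00122784
10.325397 1.41047474 0.00108564
10.460317 1.41008077 0.00097044
10.595238 1.40973490 0.00087562
10.730159 1.40942875 0.00079647
10.865079 1.40915580 0.00072959
11.000000 1.40891087 0.00067248
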