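#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Emit progress/log lines on stderr, gated by options(miescope.verbose).
msg <- function(...) {
  if (isTRUE(getOption("miescope.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

## Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards so simulation code never perturbs it.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Points are n x 3 numeric matrices throughout; accept a bare length-3
## vector for convenience.
as_points <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    points <- matrix(points, ncol = 3L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  points
}

vec_norm <- function(v) sqrt(sum(v^2))

## Stable textual fingerprint of a (possibly nested) configuration object,
## used for the output manifest.
config_hash <- function(x) {
  flat <- function(o, prefix = "") {
    if (is.list(o)) {
      nm <- names(o)
      if (is.null(nm)) nm <- seq_along(o)
      unlist(lapply(seq_along(o), function(i) {
        flat(o[[i]], paste0(prefix, ".", nm[i]))
      }))
    } else if (is.complex(o)) {
      paste0(prefix, "=", paste(sprintf("%.17g%+.17gi", Re(o), Im(o)), collapse = ","))
    } else if (is.numeric(o)) {
      paste0(prefix, "=", paste(sprintf("%.17g", o), collapse = ","))
    } else {
      paste0(prefix, "=", paste(as.character(o), collapse = ","))
    }
  }
  txt <- paste(flat(x), collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}
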