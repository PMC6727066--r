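#' Derive a stream seed from a master seed
#'
#' All stochastic subsystems (parameter initialisation, negative sampling,
#' fold splitting, simulation) draw their own seed from a single master seed
#' through a fixed labelled-offset scheme, so that any one subsystem is
#' reproducible in isolation. The derived value always fits a 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param stream one of `"init"`, `"negatives"`, `"folds"`, `"sim"`,
#'   `"scores"`, or an integer offset.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  offsets <- c(init = 101L, negatives = 211L, folds = 307L,
               sim = 401L, scores = 503L)
  off <- if (is.character(stream)) {
    if (!stream %in% names(offsets)) {
      stop("unknown seed stream: ", stream)
    }
    offsets[[stream]]
  } else {
    as.numeric(stream)
  }
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483629)
}

# shared argument checks -------------------------------------------------

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`", name, "` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("`", name, "` contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

stop_if_not_binary <- function(M, name = "M") {
  stop_if_not_matrix(M, name)
  if (!all(M %in% c(0, 1))) {
    stop("`", name, "` must contain only 0/1 entries", call. = FALSE)
  }
  invisible(M)
}
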