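#' Derive a reproducible sub-seed from a master seed
#'
#' Stages of the pipeline (and independent loci within a stage) draw their
#' randomness from named substreams so that any stage can be re-run in
#' isolation with the same result. The derivation is a small integer hash of
#' the master seed and the stream name, kept below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer((abs(seed) %% 2147483629 * 1103 + h + 17) %% 2147483629)
}

# set a seed for the calling frame only, restoring global RNG state on exit
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# enum checks -----------------------------------------------------------

INHERITANCE_MODES <- c("mitochondrial", "z_linked", "autosomal")

check_inheritance <- function(inheritance) {
  match.arg(inheritance, INHERITANCE_MODES)
}

check_alpha <- function(alpha, name = "alpha") {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort(sprintf("`%s` must be a single number in (0, 1).", name))
  }
  alpha
}
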