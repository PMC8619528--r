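# shared helpers: structured logging and seed fan-out

#' @keywords internal
gnd_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("gutnetdys.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# Per-stage child seeds derived from one global seed by a fixed counter
# scheme, so a stage rerun in isolation reproduces its in-pipeline draws.
# Kept below 2^31 - 1 for any seed the CLI accepts.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

GUT_SECTIONS <- c("midgut", "ileum", "rectum")
DOSES_PPB <- c(0, 0.1, 1, 10)

# fixed label for a dose that is stable under formatting (0.1 not "1e-01"),
# element-wise so vectors don't get a padded common format
dose_label <- function(dose) {
  vapply(dose, function(x) format(x, trim = TRUE, scientific = FALSE),
         character(1))
}
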