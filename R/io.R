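#' Read and write trial-record tables
#'
#' Trial records are plain CSV, one row per trial. `read_trials()` restores
#' the context factor with its canonical levels
#' (low/medium-low/medium-high/high/hidden) and checks the report range.
#'
#' @param trials A trial-record tibble.
#' @param path CSV file path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- as_tibble(utils::read.csv(path))
  if ("context" %in% names(d)) {
    d$context <- factor(d$context, levels = CONTEXT_LEVELS)
  }
  if ("report" %in% names(d)) assert_reports(d$report[!is.na(d$report)])
  d
}
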