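PARTNER_LEVELS <- c("low", "medium-low", "medium-high", "high")
CONTEXT_LEVELS <- c(PARTNER_LEVELS, "hidden")

# Balanced directions within a cell: exact 50/50 when the cell size is even,
# otherwise the extra trial's direction is randomised.
balanced_directions <- function(n) {
  half <- n %/% 2
  dirs <- c(rep(-1L, half), rep(1L, half))
  if (n %% 2 == 1L) dirs <- c(dirs, sample(c(-1L, 1L), 1L))
  sample(dirs)
}

#' Build a session design for one task phase
#'
#' Constructs the factorial trial list for each phase of the social
#' perceptual decision task:
#' \itemize{
#'   \item `calibration1`: 5 prespecified coherences x 20 trials x 2
#'     directions = 200 trials, no social context.
#'   \item `calibration2`: 4 calibrated coherences x 25 x 2 = 200 trials.
#'   \item `phase2`: partners met block-wise, 4 cycles of blocks of 10 trials
#'     per partner (A-B-C-D repeated; 4 x 4 x 10 = 160 trials).
#'   \item `phase3`: partners interleaved, 4 x 40 = 160 trials.
#'   \item `phase4`: adds a hidden-context condition, 5 x 40 = 200 trials.
#'   \item `scan_run`: 4 repetitions of each of the 16 signalled coherence x
#'     context conditions plus 16 hidden-context trials (4 per coherence),
#'     4 x 4 x 5 = 80 trials.
#' }
#' Coherence levels are counterbalanced within context, trial order is
#' randomised under `seed` (phase-2 block structure is preserved), and
#' directions are balanced 50/50 within each condition cell.
#'
#' @param phase One of `"calibration1"`, `"calibration2"`, `"phase2"`,
#'   `"phase3"`, `"phase4"`, `"scan_run"`.
#' @param coherences The 4 calibrated coherence levels, ascending
#'   (ignored for `calibration1`, which uses the prespecified set
#'   .03/.06/.12/.24/.48).
#' @param seed Optional seed for order randomisation.
#' @return A tibble of class `session_design` with columns `trial`, `block`
#'   (phase2 only, otherwise `NA`), `coherence_level` (1..4 index, `NA` in
#'   calibration1), `coherence`, `context` (factor with levels
#'   low/medium-low/medium-high/high/hidden; `NA` in calibration phases) and
#'   `direction` (-1/+1). The phase is stored in attribute `"phase"`.
#' @export
build_design <- function(phase, coherences, seed = NULL) {
  phases <- c("calibration1", "calibration2", "phase2", "phase3",
              "phase4", "scan_run")
  if (!is.character(phase) || length(phase) != 1L || !phase %in% phases) {
    abort(sprintf("unknown phase; must be one of: %s.",
                  paste(phases, collapse = ", ")))
  }
  if (phase != "calibration1") {
    if (length(coherences) != 4L || is.unsorted(coherences, strictly = TRUE)) {
      abort("`coherences` must be 4 strictly increasing calibrated levels.")
    }
  }
  out <- with_rng(seed, {
    if (phase %in% c("calibration1", "calibration2")) {
      ks <- if (phase == "calibration1") c(.03, .06, .12, .24, .48) else coherences
      per_dir <- if (phase == "calibration1") 20L else 25L
      d <- tidyr::expand_grid(
        coherence = ks,
        direction = c(-1L, 1L),
        rep = seq_len(per_dir)
      )
      d$coherence_level <- if (phase == "calibration1") NA_integer_
                           else match(d$coherence, coherences)
      d <- d[sample(nrow(d)), c("coherence_level", "coherence", "direction")]
      d$context <- factor(NA, levels = CONTEXT_LEVELS)
      d$block <- NA_integer_
      d
    } else if (phase == "phase2") {
      # per partner: 40 trials, 10 per coherence level, split into 4 blocks
      # of 10; blocks presented in 4 cycles of a fixed partner order.
      per_partner <- lapply(PARTNER_LEVELS, function(p) {
        cells <- lapply(1:4, function(lv) {
          tibble(coherence_level = lv, coherence = coherences[lv],
                 direction = balanced_directions(10L))
        })
        d <- dplyr::bind_rows(cells)
        d <- d[sample(nrow(d)), ]
        d$context <- factor(p, levels = CONTEXT_LEVELS)
        d$block_in_partner <- rep(1:4, each = 10L)
        d
      })
      names(per_partner) <- PARTNER_LEVELS
      blocks <- tidyr::expand_grid(cycle = 1:4, partner = PARTNER_LEVELS)
      d <- purrr::pmap_dfr(blocks, function(cycle, partner) {
        b <- per_partner[[partner]]
        b <- b[b$block_in_partner == cycle, ]
        b$block <- NA_integer_ # filled below
        b
      })
      d$block <- rep(seq_len(16L), each = 10L)
      d[, c("block", "coherence_level", "coherence", "direction", "context")]
    } else {
      contexts <- if (phase == "phase3") PARTNER_LEVELS else CONTEXT_LEVELS
      per_cell <- if (phase == "scan_run") 4L else 10L
      d <- purrr::map_dfr(contexts, function(cx) {
        purrr::map_dfr(1:4, function(lv) {
          tibble(coherence_level = lv, coherence = coherences[lv],
                 context = factor(cx, levels = CONTEXT_LEVELS),
                 direction = balanced_directions(per_cell))
        })
      })
      d <- d[sample(nrow(d)), ]
      d$block <- NA_integer_
      d
    }
  })
  out$trial <- seq_len(nrow(out))
  out <- as_tibble(out[, c("trial", "block", "coherence_level", "coherence",
                           "context", "direction")])
  attr(out, "phase") <- phase
  class(out) <- c("session_design", class(out))
  out
}
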