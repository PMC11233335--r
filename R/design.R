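#' The 2x2 design: picture pleasantness x anticipated search difficulty
#'
#' `design_cells()` returns the four cells in canonical order. Pleasantness
#' comes from the picture's valence norm (below 5 = unpleasant); difficulty
#' from the visual-search cue shown before the picture (feature searches —
#' colour or shape — are easy, conjunction search is difficult).
#'
#' @return A data frame with columns `cell`, `pleasantness`, `difficulty`.
#' @export
design_cells <- function() {
  data.frame(
    cell = c("unpleasant.easy", "unpleasant.difficult",
             "pleasant.easy", "pleasant.difficult"),
    pleasantness = c("unpleasant", "unpleasant", "pleasant", "pleasant"),
    difficulty = c("easy", "difficult", "easy", "difficult"),
    stringsAsFactors = FALSE
  )
}

#' @rdname design_cells
#' @param pleasantness,difficulty factor levels identifying a cell.
#' @export
cell_label <- function(pleasantness, difficulty) {
  ok_p <- pleasantness %in% c("pleasant", "unpleasant")
  ok_d <- difficulty %in% c("easy", "difficult")
  if (!all(ok_p)) stop("unknown pleasantness label")
  if (!all(ok_d)) stop("unknown difficulty label")
  paste(pleasantness, difficulty, sep = ".")
}

#' Collapse the search cue to anticipated difficulty
#'
#' Colour and shape cues announce a feature search (easy); the conjunction
#' cue announces a conjunction search (difficult).
#'
#' @param cue character vector with values in `color`, `shape`,
#'   `conjunction`.
#' @return `"easy"` or `"difficult"` per element.
#' @examples
#' cue_to_difficulty(c("color", "conjunction"))
#' @export
cue_to_difficulty <- function(cue) {
  cue <- as.character(cue)
  bad <- setdiff(unique(cue), c("color", "shape", "conjunction"))
  if (length(bad))
    stop("unknown search cue label(s): ", paste(bad, collapse = ", "))
  ifelse(cue == "conjunction", "difficult", "easy")
}

#' Code an emotion report as normative or aberrant
#'
#' A report is *normative* when it agrees with the picture's population
#' valence norm (1-9 scale): norms below 5 make "unpleasant" the normative
#' report, norms above 5 make "pleasant" normative. A norm of exactly 5 has
#' no normative response and is an error; the stimulus set keeps norms in
#' 2-4 and 5.5-6.5, so it cannot occur in valid data.
#'
#' @param picture_norm numeric valence norm(s) in `[1, 9]`, never exactly 5.
#' @param report `"pleasant"` or `"unpleasant"` per trial.
#' @return `"normative"` or `"aberrant"` per trial.
#' @examples
#' code_response(3.1, "unpleasant")  # "normative"
#' code_response(6.0, "unpleasant")  # "aberrant"
#' @export
code_response <- function(picture_norm, report) {
  report <- as.character(report)
  if (!all(report %in% c("pleasant", "unpleasant")))
    stop("report must be 'pleasant' or 'unpleasant'")
  if (any(!is.finite(picture_norm) | picture_norm < 1 | picture_norm > 9))
    stop("picture norms must lie in [1, 9]")
  if (any(picture_norm == 5))
    stop("picture norm of exactly 5 has no normative response")
  normative_report <- ifelse(picture_norm < 5, "unpleasant", "pleasant")
  ifelse(report == normative_report, "normative", "aberrant")
}

#' Recode normative/aberrant back to the absolute response
#'
#' Utility inverse of [code_response()]: given the picture norm, map a
#' stimulus-relative coding to the pleasant/unpleasant key press. Unused in
#' fitting, where accumulators are stimulus-relative.
#'
#' @param picture_norm valence norm(s), never exactly 5.
#' @param choice `"normative"` or `"aberrant"` per trial.
#' @return `"pleasant"` or `"unpleasant"` per trial.
#' @export
decode_response <- function(picture_norm, choice) {
  if (any(picture_norm == 5)) stop("picture norm of exactly 5 is undefined")
  normative_report <- ifelse(picture_norm < 5, "unpleasant", "pleasant")
  aberrant_report <- ifelse(picture_norm < 5, "pleasant", "unpleasant")
  ifelse(choice == "normative", normative_report, aberrant_report)
}

#' Model specification: null versus core parameter maps
#'
#' The *null* model shares all five subject-level parameters (`A`, `B`,
#' `t0`, `mean_v.normative`, `mean_v.aberrant`) across the four design
#' cells. The *core* model shares `A` and `t0` but lets the boundary gap
#' `B` and both mean drift rates vary by cell: 2 + 3 x 4 = 14 free
#' parameters per subject. The core model nests the null model — setting
#' all split parameters equal reproduces null-model likelihoods exactly.
#'
#' @param name `"core"` or `"null"`.
#' @return An object of class `model_spec` with elements `name`,
#'   `par_names`, `n_free`, `lower` (support lower bounds, `-Inf` for
#'   drifts), and the expansion map used internally.
#' @examples
#' model_spec("null")$par_names
#' @export
model_spec <- function(name = c("core", "null")) {
  name <- match.arg(name)
  cells <- design_cells()$cell
  if (name == "null") {
    par_names <- c("A", "B", "t0", "v_norm", "v_ab")
    lower <- c(0, 0, 0, -Inf, -Inf)
    # column index into theta for each of the 24 cell-parameter slots
    # (per cell: A, B, t0, sv, v_norm, v_ab; sv is a constant)
    idx <- rep(c(1L, 2L, 3L, NA, 4L, 5L), times = 4)
  } else {
    par_names <- c("A", "t0",
                   paste0("B.", cells),
                   paste0("v_norm.", cells),
                   paste0("v_ab.", cells))
    lower <- c(0, 0, rep(0, 4), rep(-Inf, 8))
    idx <- unlist(lapply(seq_along(cells), function(k) {
      c(1L, 2L + k, 2L, NA, 6L + k, 10L + k)
    }))
  }
  structure(list(name = name, par_names = par_names,
                 n_free = length(par_names), lower = lower,
                 cells = cells, idx = idx),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("LBA model spec '%s': %d free subject-level parameters\n",
              x$name, x$n_free))
  cat("  ", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

# theta rows (one per chain/draw) -> 24-column cell-parameter matrix
expand_theta_rows <- function(spec, theta, sv = 1) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != spec$n_free)
    stop("theta has ", ncol(theta), " columns; spec '", spec$name,
         "' needs ", spec$n_free)
  out <- matrix(sv, nrow(theta), 24L)
  has <- !is.na(spec$idx)
  out[, which(has)] <- theta[, spec$idx[has], drop = FALSE]
  out
}

#' Expand a free-parameter vector to per-cell parameters
#'
#' Maps a subject's free-parameter vector (in `model_spec()$par_names`
#' order) to a fully populated [cell_params()] per design cell. Shared
#' parameters take identical values in every cell; `flatten_subject_params`
#' inverts the expansion.
#'
#' @param spec a [model_spec()].
#' @param theta numeric vector of length `spec$n_free`.
#' @param sv fixed across-trial drift SD (the scaling constraint).
#' @return A named list of [cell_params()], one per cell.
#' @export
expand_subject_params <- function(spec, theta, sv = 1) {
  if (length(theta) != spec$n_free)
    stop("theta has length ", length(theta), "; spec '", spec$name,
         "' needs ", spec$n_free)
  m <- expand_theta_rows(spec, matrix(theta, nrow = 1), sv = sv)
  cells <- lapply(seq_along(spec$cells), function(k) {
    p <- m[1, 6 * (k - 1) + 1:6]
    cell_params(A = p[1], B = p[2], t0 = p[3],
                mean_v_normative = p[5], mean_v_aberrant = p[6],
                sv = p[4])
  })
  names(cells) <- spec$cells
  cells
}

#' @rdname expand_subject_params
#' @param cells a named list of per-cell [cell_params()] as produced by
#'   `expand_subject_params`.
#' @export
flatten_subject_params <- function(spec, cells) {
  g <- function(cell, field, acc = "normative") cells[[cell]][[acc]][[field]]
  c1 <- spec$cells[1]
  if (spec$name == "null") {
    c(g(c1, "A"), g(c1, "B"), g(c1, "t0"),
      g(c1, "mean_v"), g(c1, "mean_v", "aberrant"))
  } else {
    c(g(c1, "A"), g(c1, "t0"),
      vapply(spec$cells, g, numeric(1), field = "B"),
      vapply(spec$cells, g, numeric(1), field = "mean_v"),
      vapply(spec$cells, g, numeric(1), field = "mean_v",
             acc = "aberrant"),
      use.names = FALSE)
  }
}
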