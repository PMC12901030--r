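#' Enumerate the unique conditions of the three-alternative decision task
#'
#' Builds the full factorial trial list of the decision task: task framing
#' (choose the highest- vs lowest-contrast patch) crossed with every ordered
#' assignment of a contrast triplet (drawn without replacement from the five
#' linearly spaced contrast levels) to the three stimulus locations, crossed
#' with the orientation condition (all three Gabor orientations identical, or
#' all three different in any order). With the full design this yields 1080
#' unique trials from 10 unordered contrast triplets.
#'
#' @param framings Character vector of framing labels.
#' @param n_levels Number of linearly spaced contrast levels in (0, 1].
#' @param n_positions Number of stimulus locations (angular positions).
#' @param orientation_rule Either `"identical_or_all_different"` (the task's
#'   rule: 3 all-identical options plus the ordered assignments of the three
#'   distinct orientations) or `"fixed"` (a single orientation condition).
#'
#' @return A list of class `task_design` with elements `framings`,
#'   `contrast_levels`, `positions`, `orientation_set`, `trial_list` (one row
#'   per unique condition) and `n_trials`.
#' @export
#' @examples
#' d <- enumerate_design()
#' d$n_trials  # 1080
enumerate_design <- function(framings = c("high", "low"),
                             n_levels = 5, n_positions = 3,
                             orientation_rule = "identical_or_all_different") {
  if (n_levels < n_positions)
    stop("n_levels must be at least n_positions")
  if (!orientation_rule %in% c("identical_or_all_different", "fixed"))
    stop("invalid orientation_rule: ", orientation_rule)
  contrast_levels <- seq_len(n_levels) / n_levels
  positions <- seq(0, 360 - 360 / n_positions, by = 360 / n_positions)
  orientation_set <- seq(0, 180 - 180 / n_positions, by = 180 / n_positions)

  # ordered assignments of an unordered triplet to the positions
  triplets <- utils::combn(contrast_levels, n_positions)
  perms <- permutations_of(n_positions)
  ordered <- do.call(rbind, lapply(seq_len(ncol(triplets)), function(j) {
    t(apply(perms, 1L, function(p) triplets[p, j]))
  }))
  colnames(ordered) <- paste0("contrast_pos", seq_len(n_positions))

  orientations <- if (orientation_rule == "fixed") {
    matrix(orientation_set[1], nrow = 1, ncol = n_positions)
  } else {
    rbind(matrix(rep(orientation_set, each = n_positions),
                 ncol = n_positions, byrow = TRUE),
          t(apply(permutations_of(n_positions), 1L,
                  function(p) orientation_set[p])))
  }
  colnames(orientations) <- paste0("orientation_pos", seq_len(n_positions))

  grid <- expand.grid(framing = framings,
                      contrast_row = seq_len(nrow(ordered)),
                      orientation_row = seq_len(nrow(orientations)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  trial_list <- cbind(data.frame(framing = grid$framing,
                                 stringsAsFactors = FALSE),
                      ordered[grid$contrast_row, , drop = FALSE],
                      orientations[grid$orientation_row, , drop = FALSE])
  rownames(trial_list) <- NULL

  structure(list(framings = framings,
                 contrast_levels = contrast_levels,
                 positions = positions,
                 orientation_set = orientation_set,
                 n_contrast_triplets = ncol(triplets),
                 trial_list = trial_list,
                 n_trials = nrow(trial_list)),
            class = "task_design")
}

# All permutations of 1..n as rows (n is tiny here).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub), n - 1L))
  }))
}

#' Enumerate one retinotopic localizer block
#'
#' A localizer block presents a single full-contrast Gabor per trial at one of
#' the three angular positions with one of three orientations; each unique
#' position x orientation combination is repeated `reps` times and paired
#' exactly once with a central fixation flicker (the participant's detection
#' task; flicker trials are excluded from model training).
#'
#' @param n_positions,n_orientations Number of positions / orientations.
#' @param reps Repetitions of each unique combination per block.
#' @param seed Optional integer; when given, the flickered repetition of each
#'   combination and the trial order are randomized reproducibly, otherwise
#'   the first repetition carries the flicker and trials are in enumeration
#'   order.
#' @return A `data.frame` with columns `position` (degrees), `orientation`
#'   (degrees) and `flicker` (logical), one row per presentation.
#' @export
#' @examples
#' blk <- enumerate_localizer_block()
#' nrow(blk)          # 90
#' sum(blk$flicker)   # 9
enumerate_localizer_block <- function(n_positions = 3, n_orientations = 3,
                                      reps = 10, seed = NULL) {
  stopifnot(reps >= 1)
  positions <- seq(0, 360 - 360 / n_positions, by = 360 / n_positions)
  orientations <- seq(0, 180 - 180 / n_orientations, by = 180 / n_orientations)
  combos <- expand.grid(position = positions, orientation = orientations,
                        KEEP.OUT.ATTRS = FALSE)
  trials <- combos[rep(seq_len(nrow(combos)), each = reps), , drop = FALSE]
  trials$rep <- rep(seq_len(reps), times = nrow(combos))
  if (!is.null(seed)) {
    set.seed(seed)
    flick_rep <- sample.int(reps, nrow(combos), replace = TRUE)
  } else {
    flick_rep <- rep(1L, nrow(combos))
  }
  trials$flicker <- trials$rep == flick_rep[rep(seq_len(nrow(combos)),
                                                each = reps)]
  if (!is.null(seed)) trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  rownames(trials) <- NULL
  trials$rep <- NULL
  trials
}
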