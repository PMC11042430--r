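IC_CLASSES <- c("brain", "muscle", "eye", "heart", "line_noise",
                "channel_noise", "other")
IC_ARTIFACT_CLASSES <- c("muscle", "eye", "heart", "line_noise",
                         "channel_noise")

#' Per-component class-probability table
#'
#' One row per independent component, giving its probability (as a
#' percentage, 0-100) of belonging to each of seven classes: brain, muscle,
#' eye, heart, line noise, channel noise, other — the output format of
#' automated IC classifiers. Rows must sum to 100 within +/- 0.5.
#'
#' @param probs data.frame or matrix with the seven class columns.
#' @return A validated `ic_probability_table` data.frame.
#' @export
ic_probability_table <- function(probs) {
  df <- as.data.frame(probs)
  missing <- setdiff(IC_CLASSES, names(df))
  if (length(missing)) {
    stop_with("cfcdetect_validation", "missing class column(s): %s",
              paste(missing, collapse = ", "))
  }
  df <- df[IC_CLASSES]
  m <- as.matrix(df)
  if (any(m < 0 | m > 100)) {
    stop_with("cfcdetect_validation", "probabilities must lie in [0, 100]")
  }
  sums <- rowSums(m)
  bad <- which(abs(sums - 100) > 0.5)
  if (length(bad)) {
    stop_with("cfcdetect_validation",
              "IC %d: class probabilities sum to %.2f, not 100", bad[1],
              sums[bad[1]])
  }
  class(df) <- c("ic_probability_table", "data.frame")
  df
}

#' @rdname ic_probability_table
#' @param path CSV file with a header row naming the seven classes.
#' @export
read_ic_probabilities <- function(path) {
  ic_probability_table(utils::read.csv(path))
}

#' Trivial classifier stand-in for synthetic data
#'
#' Assigns `brain = 100` to every component, so all components survive
#' selection; used when the data are simulated and contain no artifacts.
#'
#' @param n_ics number of components.
#' @export
iclabel_stand_in <- function(n_ics) {
  df <- as.data.frame(matrix(0, n_ics, length(IC_CLASSES),
                             dimnames = list(NULL, IC_CLASSES)))
  df$brain <- 100
  ic_probability_table(df)
}

#' Select non-artifactual ("good") independent components
#'
#' A component is *removed* when either of two rules fires (combined with OR
#' by default):
#' \enumerate{
#'   \item any single artifact-class probability (muscle, eye, heart, line
#'     noise, channel noise) exceeds the probability of the non-artifact
#'     pool — by default, exceeds both the brain and the other probability
#'     (strictly; ties keep the component);
#'   \item the five artifact-class probabilities sum to more than 50.
#' }
#' The wording of both rules is ambiguous in two places, so both readings
#' are exposed: `combine` switches the rules between OR and AND, and
#' `nonartifact` switches the rule-1 reference between `max(brain, other)`
#' and `min(brain, other)`.
#'
#' @param table an [ic_probability_table()].
#' @param combine how the two removal rules combine: `"or"` (default) or
#'   `"and"`.
#' @param nonartifact rule-1 reference level: `"max"` (default) or `"min"`
#'   of the brain and other probabilities.
#' @return Logical vector, `TRUE` for components to keep.
#' @export
select_good_ics <- function(table, combine = c("or", "and"),
                            nonartifact = c("max", "min")) {
  combine <- match.arg(combine)
  nonartifact <- match.arg(nonartifact)
  table <- ic_probability_table(table)
  art <- as.matrix(table[IC_ARTIFACT_CLASSES])
  ref <- if (nonartifact == "max") {
    pmax(table$brain, table$other)
  } else {
    pmin(table$brain, table$other)
  }
  crit1 <- apply(art > ref, 1, any)
  crit2 <- rowSums(art) > 50
  removed <- if (combine == "or") crit1 | crit2 else crit1 & crit2
  !removed
}

#' Drop rejected components from an activation matrix
#'
#' @param acts an `ic_activations` object (see [apply_unmixing()]).
#' @param mask logical keep-mask of length equal to the component count.
#' @return The activations restricted to kept components, order preserved.
#' @export
filter_activations <- function(acts, mask) {
  if (length(mask) != nrow(acts$acts)) {
    stop_with("cfcdetect_dimension",
              "mask length %d but %d components", length(mask),
              nrow(acts$acts))
  }
  if (!any(mask)) {
    stop_with("cfcdetect_empty_selection",
              "all components of segment '%s' were rejected", acts$segment_id)
  }
  acts$acts <- acts$acts[mask, , drop = FALSE]
  acts
}
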