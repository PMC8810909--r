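#' Crowdsourced vote aggregation
#'
#' Images of squirrels are classified by multiple participants: first
#' the number of animals present ("zero", "one", "two_or_more"), then
#' the coat color of each animal ("gray", "melanic", "other",
#' "unclear"). These functions reduce the long-format vote table to
#' retained observations under a minimum-agreement rule.
#'
#' @name consensus
NULL

COUNT_LABELS <- c("zero", "one", "two_or_more")
COLOR_LABELS <- c("gray", "melanic", "other", "unclear")

#' Consensus label from a vote list
#'
#' Returns the modal label when its share of all votes (including
#' "unclear" votes in the denominator) is at least `threshold` and at
#' least `min_votes` votes were cast; otherwise `NA` (unresolved).
#' Ties at the mode are unresolved; with `threshold > 0.5` a tie can
#' never reach the threshold, this is asserted defensively.
#'
#' @param votes character vector of labels
#' @param threshold minimum agreement share, in (0.5, 1]
#' @param min_votes minimum number of votes
#' @return the consensus label, or `NA_character_` if unresolved
#' @export
consensus_label <- function(votes, threshold = 0.8, min_votes = 10L) {
  if (length(votes) == 0L) stop("empty vote list")
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  if (min_votes < 1L) stop("min_votes must be >= 1")
  if (length(votes) < min_votes) return(NA_character_)
  tab <- table(votes)
  top <- max(tab)
  if (sum(tab == top) > 1L) return(NA_character_)  # tie at the mode
  if (top / length(votes) < threshold) return(NA_character_)
  names(tab)[which.max(tab)]
}

#' Resolve one image's votes into observations
#'
#' Applies the agreement rule first to the count question, then to each
#' claimed squirrel's color votes. The image is dropped when the count
#' is unresolved or resolves to "zero"; it is retained when at least
#' one squirrel's color resolves to a real morph ("unclear" is a valid
#' vote but never a consensus outcome). Images with several squirrels
#' of different resolved morphs yield one observation per morph.
#'
#' @param record a list with elements `image_id`, `count_votes`
#'   (character), `color_votes` (list of character vectors, one per
#'   squirrel slot), and optionally `x`, `y` (or `NA` when the image
#'   has no location) and `in_native_range` (logical)
#' @param threshold,min_votes agreement rule, as [consensus_label()]
#' @return a list with `observations` (data.frame, possibly 0 rows)
#'   and `stage` (one of "failed_count", "count_zero", "failed_color",
#'   "retained")
#' @export
resolve_image <- function(record, threshold = 0.8, min_votes = 10L) {
  cnt <- consensus_label(record$count_votes, threshold, min_votes)
  empty <- data.frame(obs_id = character(0), x = numeric(0), y = numeric(0),
                      color = character(0), source = character(0),
                      in_native_range = logical(0),
                      stringsAsFactors = FALSE)
  if (is.na(cnt)) return(list(observations = empty, stage = "failed_count"))
  if (cnt == "zero") return(list(observations = empty, stage = "count_zero"))
  colors <- vapply(record$color_votes,
                   consensus_label, NA_character_,
                   threshold = threshold, min_votes = min_votes)
  colors <- colors[!is.na(colors) & colors != "unclear"]
  colors <- unique(colors)
  if (length(colors) == 0L)
    return(list(observations = empty, stage = "failed_color"))
  obs <- data.frame(
    obs_id = paste0(record$image_id, "/", colors),
    x = if (is.null(record$x)) NA_real_ else record$x,
    y = if (is.null(record$y)) NA_real_ else record$y,
    color = colors,
    source = "votes",
    in_native_range = if (is.null(record$in_native_range)) TRUE
                      else record$in_native_range,
    stringsAsFactors = FALSE)
  list(observations = obs, stage = "retained")
}

#' Aggregate a long-format vote table into observations
#'
#' @param votes data.frame with columns `image_id`, `question` ("count"
#'   or "color"), `slot` (squirrel index within the image; ignored for
#'   count votes), `label`, and optionally `voter_id`; image locations
#'   and range flags are supplied via `images`
#' @param images optional data.frame with columns `image_id`, `x`, `y`,
#'   `in_native_range`
#' @param threshold,min_votes agreement rule
#' @return list with `observations` (all resolved, pre-filter) and
#'   `report` (a [consensus_report()]); pass the observations through
#'   [filter_observations()] to apply the location / range filters
#' @export
resolve_votes <- function(votes, images = NULL, threshold = 0.8,
                          min_votes = 10L) {
  stopifnot(all(c("image_id", "question", "label") %in% names(votes)))
  if (is.null(votes$slot)) votes$slot <- 1L
  ids <- unique(votes$image_id)
  meta <- NULL
  if (!is.null(images)) meta <- images[match(ids, images$image_id), ]
  out <- vector("list", length(ids))
  stages <- character(length(ids))
  counts <- character(length(ids))
  by_img <- split(seq_len(nrow(votes)), votes$image_id)
  for (k in seq_along(ids)) {
    rows <- votes[by_img[[as.character(ids[k])]], ]
    rec <- list(
      image_id = ids[k],
      count_votes = rows$label[rows$question == "count"],
      color_votes = split(rows$label[rows$question == "color"],
                          rows$slot[rows$question == "color"]))
    if (!is.null(meta)) {
      rec$x <- meta$x[k]; rec$y <- meta$y[k]
      rec$in_native_range <- meta$in_native_range[k]
    }
    res <- resolve_image(rec, threshold, min_votes)
    cnt <- consensus_label(rec$count_votes, threshold, min_votes)
    counts[k] <- if (is.na(cnt)) "unresolved" else cnt
    out[[k]] <- res$observations
    stages[k] <- res$stage
  }
  obs <- do.call(rbind, out)
  report <- list(
    submitted = length(ids),
    met_count_threshold = sum(stages != "failed_count"),
    count_zero = sum(counts == "zero"),
    count_one = sum(counts == "one"),
    count_two_plus = sum(counts == "two_or_more"),
    met_color_threshold = sum(stages == "retained"),
    resolved_observations = if (is.null(obs)) 0L else nrow(obs))
  if (is.null(obs))
    obs <- data.frame(obs_id = character(0), x = numeric(0), y = numeric(0),
                      color = character(0), source = character(0),
                      in_native_range = logical(0), stringsAsFactors = FALSE)
  list(observations = obs, report = report)
}

#' Filter resolved observations and complete the stage report
#'
#' Drops observations with missing coordinates, then those flagged
#' outside the species' native range. Counts are tallied per image
#' group (an image's observations are kept or dropped together since
#' location and range are image properties).
#'
#' @param obs data.frame as produced by [resolve_votes()]
#' @param report optional partial report list to extend
#' @return list with `observations` (retained rows) and `report`
#' @export
filter_observations <- function(obs, report = list()) {
  has_loc <- !(is.na(obs$x) | is.na(obs$y))
  in_range <- if (is.null(obs$in_native_range)) rep(TRUE, nrow(obs))
              else obs$in_native_range & !is.na(obs$in_native_range)
  keep <- has_loc & in_range
  report$dropped_no_location <- sum(!has_loc)
  report$dropped_out_of_range <- sum(has_loc & !in_range)
  report$final <- sum(keep)
  res <- obs[keep, , drop = FALSE]
  rownames(res) <- NULL
  list(observations = res, report = report)
}

#' Merge vote-derived and directly reported observations
#'
#' @param vote_obs,direct_obs data.frames sharing the observation
#'   schema (`obs_id`, `x`, `y`, `color`, `source`)
#' @return row-bound data.frame with globally unique `obs_id`
#' @export
merge_sources <- function(vote_obs, direct_obs) {
  common <- intersect(names(vote_obs), names(direct_obs))
  if (nrow(direct_obs) == 0L) return(vote_obs)
  dup <- intersect(vote_obs$obs_id, direct_obs$obs_id)
  if (length(dup) > 0L)
    stop("duplicate obs_id across sources: ", paste(utils::head(dup, 5L),
                                                    collapse = ", "))
  out <- rbind(vote_obs[common], direct_obs[common])
  rownames(out) <- NULL
  out
}
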