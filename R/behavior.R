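# Recognition-memory scoring: arcsine parametric modulator and
# confidence-rating ROC/AUC.

#' Construct a rating table
#'
#' @param item_id Item identifiers.
#' @param status Factor/character, `"old"` or `"new"`.
#' @param rating Integer 1-5 recognition-confidence rating
#'   (1 = sure new ... 5 = sure old).
#' @return A data frame of class `rating_table`.
#' @export
rating_table <- function(item_id, status, rating) {
  status <- as.character(status)
  stopifnot_msg(all(status %in% c("old", "new")),
                "status must be 'old' or 'new'")
  stopifnot_msg(all(rating %in% 1:5), "ratings must be integers in 1..5")
  structure(data.frame(item_id = item_id, status = status,
                       rating = as.integer(rating)),
            class = c("rating_table", "data.frame"))
}

#' Arcsine subsequent-memory parametric modulator
#'
#' Maps a 5-point recognition-confidence rating \eqn{x \in \{1..5\}} to
#' \deqn{PM = \arcsin\!\left(\frac{x - 3}{2}\right)\cdot\frac{2}{\pi},}
#' so that \eqn{-1 \le PM \le +1} with PM(1) = -1, PM(3) = 0, PM(5) = +1.
#' Relative to a linear recoding, the arcsine puts more weight on
#' high-confidence ("sure old"/"sure new") responses.
#'
#' @param rating Integer vector with values in 1..5.
#' @return Numeric vector of PM values in \[-1, 1\].
#' @export
#' @examples
#' parametric_modulator(1:5)
parametric_modulator <- function(rating) {
  stopifnot_msg(length(rating) > 0 && all(rating %in% 1:5),
                "ratings must be integers in 1..5")
  asin((rating - 3) / 2) * 2 / pi
}

#' Recognition-memory AUC from confidence ratings
#'
#' Plots cumulative hit proportions (old items rated at or above each
#' criterion >=5, >=4, >=3, >=2) against cumulative false-alarm proportions
#' (same criteria on new items), closes the curve with (0,0) and (1,1), and
#' integrates by the trapezoidal rule. Equivalent to the tie-corrected
#' Mann-Whitney statistic \eqn{U/(n_{old} n_{new})}. 0.5 is chance
#' discrimination.
#'
#' @param ratings A [rating_table] (or data frame with `status`, `rating`).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(ratings) {
  old <- ratings$rating[ratings$status == "old"]
  new <- ratings$rating[ratings$status == "new"]
  stopifnot_msg(length(old) >= 1 && length(new) >= 1,
                "need at least one old and one new item")
  crit <- 5:2
  hits <- vapply(crit, function(k) mean(old >= k), 0)
  fas <- vapply(crit, function(k) mean(new >= k), 0)
  x <- c(0, fas, 1)
  y <- c(0, hits, 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
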