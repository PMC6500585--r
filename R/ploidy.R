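#' Sturges class width from range and sample size
#'
#' Evaluates `R / (1 + 3.322 * log10(N))`: the range of a statistical series
#' divided by the Sturges number of classes.
#'
#' @param range_R range of the series (max - min), >= 0.
#' @param n_items number of items N, >= 1.
#' @return Class width in the units of `range_R`.
#' @examples
#' sturges_width(118 - 15, 594)  # ~10.08
#' @export
sturges_width <- function(range_R, n_items) {
  if (n_items < 1) stop("n_items must be >= 1")
  if (range_R < 0) stop("range_R must be >= 0")
  range_R / (1 + 3.322 * log10(n_items))
}

roman <- function(k) as.character(utils::as.roman(k))

#' Bin nuclear volumes into contiguous size classes
#'
#' Classes are half-open `[anchor + (k-1)*width, anchor + k*width)` starting
#' at the anchor; values below the anchor fold into class I, and a value
#' landing exactly on the top boundary of the covering range joins the last
#' class (so a 20..220 um^3 population with 25 um^3 classes yields exactly
#' eight). Defaults (width 25, anchor 20) reproduce the printed class limits
#' 20-45, 45-70, ..., 195-220.
#'
#' @param volumes numeric vector of volumes in um^3.
#' @param width class width in um^3.
#' @param anchor lower bound of class I in um^3.
#' @return List: `classes` (data.frame index, label, lower, upper,
#'   putative_ploidy, n, mean_volume, sd_volume) and `assignment` (class index
#'   per input value).
#' @export
bin_classes <- function(volumes, width = 25, anchor = 20) {
  stopifnot(width > 0)
  if (!length(volumes))
    return(list(classes = data.frame(index = integer(), label = character(),
                                     lower = numeric(), upper = numeric(),
                                     putative_ploidy = character(),
                                     n = integer(), mean_volume = numeric(),
                                     sd_volume = numeric()),
                assignment = integer()))
  n_classes <- max(1L, ceiling((max(volumes) - anchor) / width))
  k <- floor((volumes - anchor) / width) + 1L
  k[k < 1L] <- 1L           # fold sub-anchor values into class I
  k[k > n_classes] <- n_classes   # exact top boundary joins the last class
  cls <- data.frame(
    index = seq_len(n_classes),
    label = roman(seq_len(n_classes)),
    lower = anchor + (seq_len(n_classes) - 1L) * width,
    upper = anchor + seq_len(n_classes) * width,
    putative_ploidy = class_to_ploidy(seq_len(n_classes)),
    n = as.integer(tabulate(k, n_classes)),
    mean_volume = vapply(seq_len(n_classes), function(i)
      if (any(k == i)) mean(volumes[k == i]) else NA_real_, 0),
    sd_volume = vapply(seq_len(n_classes), function(i)
      if (sum(k == i) > 1) sd(volumes[k == i]) else NA_real_, 0))
  list(classes = cls, assignment = k)
}

#' Putative ploidy label for a volume class
#'
#' Class I maps to 2C, class II to 4C, ... class k to `2^k C`: each class up
#' doubles the putative DNA content, matching one endoreduplication round.
#'
#' @param class_index integer vector of class indices (>= 1).
#' @return Character vector of labels ("2C", "4C", ...).
#' @export
class_to_ploidy <- function(class_index) {
  stopifnot(all(class_index >= 1))
  paste0(2^class_index, "C")
}
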