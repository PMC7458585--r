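#' Normalize hashtag spellings
#'
#' Hashtags are case-insensitive; comparison strips the leading "#", trims
#' whitespace and case-folds.
#' @param tag character vector of tags, with or without a leading "#".
#' @return lower-case bare tag names.
#' @export
normalize_tag <- function(tag) {
  tolower(sub("^#", "", trimws(as.character(tag))))
}

#' Hashtag frequency shares
#'
#' Computes each tag's exact share of the table's grand total and the
#' display share: the percentage rounded half-up to one decimal, the form
#' used in published hashtag tables. The denominator is always the supplied
#' table's grand total, never an external platform total; counts are posts,
#' not distinct users.
#'
#' @param x data.frame with columns \code{tag} and \code{count} (and
#'   optionally \code{group}); counts are non-negative integers, at least
#'   one positive; tags unique after case-folding.
#' @return an object of class \code{"hashtag_shares"}: the input plus
#'   \code{exact_share} (fraction) and \code{display_share} (percent, one
#'   decimal), with the grand total as an attribute.
#' @examples
#' shares(data.frame(tag = c("#a", "#b"), count = c(1, 3)))
#' @export
shares <- function(x) {
  stopifnot(is.data.frame(x), all(c("tag", "count") %in% names(x)))
  if (any(is.na(x$count) | x$count < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (sum(x$count) == 0) stop("all counts are zero", call. = FALSE)
  if (anyDuplicated(normalize_tag(x$tag)))
    stop("duplicate tag(s) after case-folding", call. = FALSE)
  grand <- sum(x$count)
  x$exact_share <- x$count / grand
  x$display_share <- round_half_up(100 * x$exact_share, 1)
  structure(x, grand_total = grand,
            class = c("hashtag_shares", "data.frame"))
}

#' @export
print.hashtag_shares <- function(x, ...) {
  cat(sprintf("Hashtag shares (grand total %s posts)\n",
              format(attr(x, "grand_total"), big.mark = ",")))
  show <- data.frame(tag = x$tag, count = format(x$count, big.mark = ","),
                     share_pct = sprintf("%.1f", x$display_share))
  print.data.frame(show[order(-x$count), ], row.names = FALSE)
  invisible(x)
}

#' Combined share of a subset of hashtags
#'
#' Two conventions are supported. \code{"sum_of_rounded"} adds the
#' individually rounded display shares (the convention seen in published
#' summaries, e.g. 35.6 + 30.5 = 66.1); \code{"exact"} rounds the exact
#' combined ratio once (the numerically honest alternative, which can
#' differ in the last decimal: 66.2 for the same pair). Both are reported
#' with the combined raw count.
#'
#' @param x a \code{"hashtag_shares"} object (or table acceptable to
#'   [shares()]).
#' @param subset character vector of tags (matched after case-folding);
#'   must all be present in the table.
#' @param method \code{"sum_of_rounded"} (paper-compatible) or
#'   \code{"exact"}.
#' @return list with \code{share} (percent, one decimal), \code{count}
#'   (combined raw count) and \code{method}.
#' @export
combined_share <- function(x, subset,
                           method = c("sum_of_rounded", "exact")) {
  method <- match.arg(method)
  if (!inherits(x, "hashtag_shares")) x <- shares(x)
  want <- normalize_tag(subset)
  have <- normalize_tag(x$tag)
  if (!all(want %in% have))
    stop("unknown tag(s): ",
         paste(subset[!want %in% have], collapse = ", "), call. = FALSE)
  sel <- have %in% want
  cnt <- sum(x$count[sel])
  share <- if (method == "sum_of_rounded") {
    round_half_up(sum(x$display_share[sel]), 1)
  } else {
    round_half_up(100 * cnt / attr(x, "grand_total"), 1)
  }
  list(share = share, count = cnt, method = method)
}

#' Display counts as multiples of a base
#'
#' Rescales large counts to "multiples of 100,000" (or another base) with
#' two decimals, the display convention of country-level hashtag tables
#' (963,000 posts -> 9.63).
#'
#' @param count non-negative counts.
#' @param base positive display base (default 100000).
#' @return numeric, \code{count / base} rounded half-up to 2 decimals.
#' @examples
#' to_multiples(963000)  # 9.63
#' @export
to_multiples <- function(count, base = 100000) {
  stopifnot(all(count >= 0), base > 0)
  round_half_up(count / base, 2)
}

#' Per-group hashtag totals and shares
#'
#' Sums counts within each group label (e.g. scientific / infodemic /
#' health / other) and reports each group's share of the grand total.
#'
#' @param x data.frame with columns \code{tag}, \code{count}, \code{group}.
#' @return data.frame with one row per group: \code{group}, \code{total},
#'   \code{share}.
#' @export
group_summary <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("count", "group") %in% names(x)))
  tot <- tapply(x$count, x$group, sum)
  data.frame(group = names(tot), total = as.numeric(tot),
             share = as.numeric(tot) / sum(x$count), row.names = NULL)
}
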