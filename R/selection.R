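# Tie-inclusive top-k selection sets and cross-year / cross-trait overlap:
# the arithmetic behind indirect-selection coincidence checks (does
# selecting on an easy proxy trait in one year recover the lines a breeder
# would want for the target trait?).

#' Tie-inclusive top-k selection set
#'
#' Members are all genotypes whose value ties or beats the k-th ranked
#' value, so boundary ties are never split: a nominal top-10 can hold more
#' than 10 lines when values repeat (rounded trait scales do this often).
#' The set is minimal subject to that rule and never shrinks as k grows.
#'
#' @param values Named numeric vector (names = genotype ids); `NA`s are
#'   ignored.
#' @param k Nominal rank depth (>= 1).
#' @param direction `"high"` (higher is better, default) or `"low"`.
#' @return A `selection_set` list: members (ids), k, threshold, direction,
#'   n_scored.
#' @export
top_k <- function(values, k, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.null(names(values)))
    stop("values must be named by genotype id", call. = FALSE)
  v <- values[!is.na(values)]
  if (!length(v)) stop("all values missing", call. = FALSE)
  sorted <- sort(v, decreasing = (direction == "high"))
  thr <- unname(sorted[min(k, length(sorted))])
  members <- if (direction == "high") names(v)[v >= thr] else
    names(v)[v <= thr]
  structure(list(members = members, k = as.integer(k), threshold = thr,
                 direction = direction, n_scored = length(v)),
            class = "selection_set")
}

#' @export
print.selection_set <- function(x, ...) {
  cat(sprintf("selection_set: %d member(s) at nominal k = %d (%s is better)\n",
              length(x$members), x$k,
              if (x$direction == "high") "higher" else "lower"))
  invisible(x)
}

.round_half_up <- function(x) floor(x + 0.5)

#' Overlap between two selection sets
#'
#' Intersection count and the percentage of the *first* (selecting) set
#' recovered in the second, rounded half-up to an integer. The percentage is
#' asymmetric by construction; the denominator is reported explicitly.
#'
#' @param a,b `selection_set` objects (or plain character vectors of ids)
#'   over the same genotype namespace.
#' @return List: size_a, size_b, intersection, percentage, denominator.
#' @export
overlap <- function(a, b) {
  ma <- if (inherits(a, "selection_set")) a$members else as.character(a)
  mb <- if (inherits(b, "selection_set")) b$members else as.character(b)
  if (!length(ma) || !length(mb))
    stop("empty selection set", call. = FALSE)
  inter <- length(intersect(ma, mb))
  list(size_a = length(ma), size_b = length(mb), intersection = inter,
       percentage = .round_half_up(100 * inter / length(ma)),
       denominator = "size_a")
}

#' Indirect-selection overlap report
#'
#' Quantifies how well top-k selection on a proxy trait coincides with top-k
#' selection on a target trait, across two years and on across-year means.
#' Four comparisons are emitted: proxy(year1) -> target(year2), proxy(mean)
#' -> target(mean), target(year1) -> target(year2) (direct-selection
#' repeatability), and proxy(year1) -> proxy(year2) (proxy repeatability).
#' Percentages are relative to the first (selecting) set.
#'
#' @param pheno Long-format phenotype data frame.
#' @param proxy_trait,target_trait Trait names present in both years.
#' @param years Length-2 character vector of year labels (default: first two
#'   years present).
#' @param k Nominal rank depth (default 10).
#' @param direction Passed to [top_k()].
#' @return Data frame: comparison, set_a, set_b, size_a, size_b,
#'   intersection, percentage.
#' @export
indirect_selection_report <- function(pheno, proxy_trait, target_trait,
                                      years = NULL, k = 10,
                                      direction = "high") {
  for (tr in unique(c(proxy_trait, target_trait))) {
    if (!tr %in% pheno$trait) stop("trait not present: ", tr, call. = FALSE)
  }
  em_p <- entry_means(pheno, proxy_trait)
  em_t <- entry_means(pheno, target_trait)
  if (is.null(years))
    years <- utils::head(setdiff(names(em_p), c("genotype", "across")), 2)
  if (length(years) != 2 || !all(years %in% names(em_p)) ||
      !all(years %in% names(em_t)))
    stop("both traits must be observed in two shared years", call. = FALSE)
  vec <- function(em, col) stats::setNames(em[[col]], em$genotype)
  sel <- function(em, col) top_k(vec(em, col), k, direction)

  combos <- list(
    c("proxy_y1_to_target_y2", "proxy", years[1], "target", years[2]),
    c("proxy_mean_to_target_mean", "proxy", "across", "target", "across"),
    c("target_y1_to_target_y2", "target", years[1], "target", years[2]),
    c("proxy_y1_to_proxy_y2", "proxy", years[1], "proxy", years[2]))
  rows <- lapply(combos, function(cb) {
    ea <- if (cb[2] == "proxy") em_p else em_t
    eb <- if (cb[4] == "proxy") em_p else em_t
    ov <- overlap(sel(ea, cb[3]), sel(eb, cb[5]))
    data.frame(comparison = cb[1],
               set_a = paste0(if (cb[2] == "proxy") proxy_trait else
                 target_trait, ":", cb[3]),
               set_b = paste0(if (cb[4] == "proxy") proxy_trait else
                 target_trait, ":", cb[5]),
               size_a = ov$size_a, size_b = ov$size_b,
               intersection = ov$intersection, percentage = ov$percentage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "k") <- k
  out
}
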