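# Distribution comparison between RNA fractions, and the qPCR ratio.

#' Wilcoxon rank-sum comparison of two ratio collections
#'
#' Two-sample Wilcoxon (Mann-Whitney) test as used to compare SS-ratio or
#' intron/exon-ratio distributions between RNA fractions. For combined
#' `n <= 20` the null distribution of the rank-sum statistic is enumerated
#' exactly over all assignments of the pooled midranks (so ties are handled
#' exactly); larger samples use the normal approximation with the usual tie
#' correction (no continuity correction). If all pooled values are identical
#' the p-value is 1.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (direction of `a` relative to `b`).
#' @param exact force (TRUE) or forbid (FALSE) exact enumeration; default
#'   enumerates when `length(a) + length(b) <= 20`.
#' @return An object of class `htest` with the Mann-Whitney `U` statistic of
#'   `a` and the p-value.
#' @examples
#' compare_fractions(c(1, 2), c(3, 4), alternative = "less")$p.value  # 1/6
#' @export
compare_fractions <- function(a, b,
                              alternative = c("two.sided", "less", "greater"),
                              exact = NULL) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both collections must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("NA values in input")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  method <- "Wilcoxon rank-sum test"

  if (length(unique(pooled)) == 1L) {
    p <- 1
  } else if (isTRUE(exact) || (is.null(exact) && n <= 20L)) {
    method <- paste(method, "(exact enumeration)")
    Us <- utils::combn(n, na, FUN = function(i) sum(r[i])) - na * (na + 1) / 2
    eps <- sqrt(.Machine$double.eps)
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
      less = mean(Us <= U + eps),
      greater = mean(Us >= U - eps))
  } else {
    method <- paste(method, "(normal approximation, tie-corrected)")
    tie <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = min(1, 2 * stats::pnorm(-abs(z))),
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE))
  }
  structure(list(
    statistic = c(U = U),
    p.value = p,
    alternative = alternative,
    method = method,
    data.name = "a vs b"
  ), class = "htest")
}

#' qPCR unspliced/spliced RNA ratio
#'
#' Converts paired Ct values from intron-exon (unspliced) and exon-exon
#' (spliced) junction amplicons into the unspliced-to-spliced abundance ratio
#' `efficiency^(ct_spliced - ct_unspliced)` (a lower Ct means more template).
#'
#' @param ct_unspliced,ct_spliced cycle-threshold values (vectors recycle).
#' @param efficiency amplification factor per cycle (default 2, perfect
#'   doubling); must exceed 1.
#' @return Numeric ratio(s) of unspliced to spliced RNA.
#' @examples
#' qpcr_ratio(22, 20)  # 0.25
#' @export
qpcr_ratio <- function(ct_unspliced, ct_spliced, efficiency = 2) {
  if (any(!is.finite(ct_unspliced)) || any(!is.finite(ct_spliced)))
    stop("non-finite Ct value")
  if (any(efficiency <= 1)) stop("efficiency must be > 1")
  efficiency^(ct_spliced - ct_unspliced)
}

#' Read a qPCR Ct table and append the unspliced/spliced ratio
#'
#' @param path TSV with columns `sample`, `ct_unspliced`, `ct_spliced`.
#' @param efficiency amplification factor per cycle.
#' @return The table with a `ratio` column appended.
#' @export
read_qpcr <- function(path, efficiency = 2) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "ct_unspliced", "ct_spliced")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("qPCR table lacks column(s): ", paste(miss, collapse = ", "))
  tab$ratio <- qpcr_ratio(tab$ct_unspliced, tab$ct_spliced, efficiency)
  tab
}
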