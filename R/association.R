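ihc_levels <- c("-", "+", "++", "+++", "++++")

#' Semiquantitative IHC score from percent positive cells
#'
#' Five-bin scheme over the percentage of MCT4-positive cancer cells:
#' 0 -> `-`; (0, 10] -> `+`; (10, 50] -> `++`; (50, 90] -> `+++`;
#' above 90 -> `++++`. Boundaries fall in the lower bin.
#'
#' @param percent Percentage(s) in `[0, 100]`.
#' @return Ordered factor over `-`, `+`, `++`, `+++`, `++++`.
#' @examples
#' ihc_score_from_percent(c(0, 5, 50, 75, 95))
#' @export
ihc_score_from_percent <- function(percent) {
  if (any(is.na(percent)) || any(percent < 0 | percent > 100)) {
    stop("IHC percent must lie in [0, 100]", call. = FALSE)
  }
  idx <- findInterval(percent, c(-Inf, 0, 10, 50, 90), left.open = TRUE)
  factor(ihc_levels[idx], levels = ihc_levels, ordered = TRUE)
}

#' Parse an IHC score annotation
#'
#' Accepts the five ordinal grades in ASCII (`-`, `+`, `++`, ...) or
#' spaced/unicode forms (`+ + +`, `−`), mixed entries such as
#' `"- and ++++"` (resolved to the maximum component) and qualifiers such
#' as `"++ (local)"`.
#'
#' @param text Character vector of score annotations.
#' @return Ordered factor over the five grades.
#' @export
parse_ihc_score <- function(text) {
  one <- function(s) {
    s <- gsub("−", "-", s)          # unicode minus
    s <- gsub("\\(.*?\\)", "", s)        # qualifiers like (local)
    parts <- strsplit(s, "(?i)\\band\\b|/|,", perl = TRUE)[[1L]]
    grades <- vapply(parts, function(p) {
      p <- gsub("[^+-]", "", p)
      if (!nzchar(p)) return(NA_integer_)
      if (grepl("-", p) && !grepl("\\+", p)) return(1L)
      n_plus <- nchar(gsub("-", "", p))
      if (n_plus >= 1L && n_plus <= 4L) n_plus + 1L else NA_integer_
    }, integer(1))
    grades <- grades[!is.na(grades)]
    if (!length(grades)) {
      stop("unresolvable IHC score: '", s, "'", call. = FALSE)
    }
    max(grades)
  }
  idx <- vapply(as.character(text), one, integer(1))
  factor(ihc_levels[idx], levels = ihc_levels, ordered = TRUE)
}

#' Strong MCT4 positivity of a tissue record
#'
#' A tissue is strongly MCT4-positive when its ordinal IHC score is at least
#' `+++` (the "score > 3+" convention includes `+++`); mixed entries resolve
#' to their maximum component via [parse_ihc_score()].
#'
#' @param record List or one-row data.frame with `ihc_score` and/or
#'   `ihc_percent`.
#' @return `TRUE`/`FALSE`.
#' @export
strong_positive <- function(record) {
  rec <- as.list(record)
  score <- rec$ihc_score
  if (is.null(score) || !length(score) || is.na(score) ||
      !nzchar(as.character(score))) {
    if (is.null(rec$ihc_percent) || is.na(rec$ihc_percent)) {
      stop("tissue record has neither IHC score nor percent", call. = FALSE)
    }
    score <- ihc_score_from_percent(rec$ihc_percent)
  }
  if (!is.factor(score)) score <- parse_ihc_score(as.character(score))
  unname(score >= "+++")
}

#' Read a tissue cohort table
#'
#' TSV mirroring the cohort layout: `id`, `histology`, `site` (`P` primary /
#' `M` metastasis), `mutation_status` (`none`, `homoplasmy`,
#' `heteroplasmy_or_heterogeneous`), and `ihc_score` and/or `ihc_percent`;
#' extra columns (gene, mutation, evidence) pass through.
#'
#' @param path Cohort TSV.
#' @return Validated data.frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("id", "mutation_status"), names(tab))
  if (length(miss)) {
    stop("cohort TSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- c("none", "homoplasmy", "heteroplasmy_or_heterogeneous")
  if (!all(tab$mutation_status %in% ok)) {
    stop("mutation_status must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tab$ihc_score) && is.null(tab$ihc_percent)) {
    stop("cohort needs an ihc_score or ihc_percent column", call. = FALSE)
  }
  tab
}

#' Mutation x strong-MCT4 contingency table
#'
#' Rows: mutation-bearing (`homoplasmy` or `heteroplasmy_or_heterogeneous`)
#' vs `none`; columns: strongly MCT4-positive vs not. Cell counts always sum
#' to the cohort size.
#'
#' @param records Cohort data.frame (see [read_cohort()]).
#' @return 2x2 integer matrix with dimnames.
#' @export
build_mutation_mct4_table <- function(records) {
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(mutation = c("mutation", "none"),
                                mct4 = c("strong", "not_strong")))
  if (!nrow(records)) return(tab)
  strong <- vapply(seq_len(nrow(records)), function(i) {
    strong_positive(records[i, , drop = FALSE])
  }, logical(1))
  has_mut <- records$mutation_status != "none"
  tab["mutation", "strong"] <- sum(has_mut & strong)
  tab["mutation", "not_strong"] <- sum(has_mut & !strong)
  tab["none", "strong"] <- sum(!has_mut & strong)
  tab["none", "not_strong"] <- sum(!has_mut & !strong)
  tab
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' \deqn{\chi^2 = N \left( \max(0, |ad - bc| - N/2) \right)^2 /
#'   \left[(a+b)(c+d)(a+c)(b+d)\right]}
#' with the continuity correction clamped at zero, and an upper-tail
#' p-value on one degree of freedom.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List of class `contingency_result`: `table`, `chi2`, `p`, `df`.
#' @examples
#' chi2_yates(matrix(c(8, 1, 1, 7), 2, byrow = TRUE))
#' @export
chi2_yates <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || sum(table) < 1) {
    stop("table cells must be non-negative with a positive total",
         call. = FALSE)
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("chi-square statistic undefined: a table margin is zero",
         call. = FALSE)
  }
  num <- max(0, abs(a * d - b * c) - n / 2)
  chi2 <- n * num^2 / prod(margins)
  structure(list(table = table, chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 df = 1L),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("Yates-corrected chi-square = %.4g, df = 1, p = %.4g\n",
              x$chi2, x$p))
  invisible(x)
}

#' Exact Mann-Whitney U test
#'
#' U is computed from midranks (tie-aware). For `n1 + n2 <= 16` the
#' two-sided p-value is exact: all `choose(n1+n2, n1)` group labelings are
#' enumerated and the p-value is the probability mass of labelings whose U
#' lies at least as far from the null mean `n1*n2/2` as the observed U.
#' For larger samples a normal approximation with tie correction and
#' continuity correction is used; `method` records which route ran.
#'
#' @param group1,group2 Numeric vectors of measurements (non-empty).
#' @param exact_limit Largest combined size for the exact route (default 16).
#' @return List of class `mann_whitney_result`: `u` (U for group 1), `p`,
#'   `n1`, `n2`, `method`.
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(10, 11, 12))  # p = 0.1 (= 2/20)
#' @export
mann_whitney_exact <- function(group1, group2, exact_limit = 16L) {
  stopifnot(length(group1) > 0L, length(group2) > 0L)
  n1 <- length(group1); n2 <- length(group2)
  pooled <- c(group1, group2)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_limit) {
    sel <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact_enumeration"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approx"
  }
  structure(list(u = u_obs, p = p, n1 = n1, n2 = n2, method = method),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$u, x$n1, x$n2, x$p, x$method))
  invisible(x)
}
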