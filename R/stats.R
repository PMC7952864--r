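#' Exact Mann-Whitney U test for small samples
#'
#' U is computed from pooled mid-ranks (tie-safe). For combined sample
#' sizes up to `exact_limit` the null distribution is the exact
#' permutation distribution over all C(n1+n2, n1) group assignments of
#' the observed pooled values, enumerated by dynamic programming over
#' the (doubled, hence integer) mid-rank sums; larger samples fall back
#' to the normal approximation with tie correction. The two-sided p is
#' 2 min(P(U <= u), P(U >= u)), capped at 1, which equals 1 when U sits
#' at the center n1 n2 / 2.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit combined-size cap for exact enumeration
#'   (default 25).
#' @return tibble: U (first sample), p (two-sided), method.
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 25L) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) abort("Samples must be non-empty.")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_limit) {
    dist <- midrank_sum_distribution(2 * r, n1)
    w2 <- round(2 * w_obs)
    p_le <- sum(dist$count[dist$sum2 <= w2]) / sum(dist$count)
    p_ge <- sum(dist$count[dist$sum2 >= w2]) / sum(dist$count)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    method <- "normal-approx"
  }
  tibble(U = u_obs, p = p, method = method)
}

# counts of subsets of size n1 by doubled-mid-rank sum (exact, tie-safe)
midrank_sum_distribution <- function(r2, n1) {
  r2 <- as.integer(round(r2))
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # f[j+1, s+1] = number of size-j subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (v in r2) {
    jmax <- n1
    for (j in jmax:1L) {
      src <- f[j, ]
      if (any(src > 0)) {
        shifted <- c(rep(0, v), src)[seq_len(smax + 1L)]
        f[j + 1L, ] <- f[j + 1L, ] + shifted
      }
    }
  }
  sums <- which(f[n1 + 1L, ] > 0) - 1L
  tibble(sum2 = sums, count = f[n1 + 1L, sums + 1L])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of p_(j) m / j,
#' capped at 1, returned in input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return numeric q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  bad <- !is.na(p) & (!is.finite(p) | p < 0 | p > 1)
  if (any(bad)) abort("p-values must lie in [0, 1].")
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation with exact or t-approximate p
#'
#' rho is the Pearson correlation of mid-ranks. For n <= `exact_limit`
#' the two-sided p can be computed exactly by enumerating all n!
#' permutations (tie-safe); otherwise (or with method = "tapprox") the
#' Student-t approximation with n - 2 degrees of freedom is used, the
#' convention of common statistics packages.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @param method "auto" (exact when n <= `exact_limit`), "exact", or
#'   "tapprox".
#' @param exact_limit size cap for permutation enumeration (default 8).
#' @return tibble: rho, p, method. Constant input gives rho = NA.
#' @export
spearman_rho <- function(x, y, method = c("auto", "exact", "tapprox"),
                         exact_limit = 8L) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant vector: Spearman rho undefined.")
    return(tibble(rho = NA_real_, p = NA_real_, method = "undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (method == "exact" || (method == "auto" && n <= exact_limit)) {
    perms <- all_permutations(n)
    # rho is monotone in sum(rx * ry_perm) for fixed marginals
    ry_perm <- matrix(ry[perms], nrow = nrow(perms))
    s_perm <- as.numeric(ry_perm %*% rx)
    rho_perm <- (s_perm - n * mean(rx) * mean(ry)) /
      ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    used <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    used <- "tapprox"
  }
  tibble(rho = rho, p = p, method = used)
}

# all permutations of 1..n as an (n! x n) matrix of positions;
# row %*% v permutes v
all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Compare two patient groups over a list of measures
#'
#' Per measure: group medians and ranges plus the exact Mann-Whitney
#' two-sided p; Benjamini-Hochberg adjustment is applied across the
#' full measure list and rows are flagged significant at the given
#' FDR level.
#'
#' @param metrics wide per-subject tibble (e.g. from
#'   [subject_metrics()]) including a group column.
#' @param measures character vector of measure column names.
#' @param groups length-2 character: the two group labels (A, B).
#' @param group_col name of the group column (default "group").
#' @param fdr FDR level for the significance flag (default 0.1).
#' @return tibble: measure, median_a/min_a/max_a, median_b/min_b/max_b,
#'   U, p, q, significant.
#' @export
group_compare <- function(metrics, measures, groups = c("LG", "HG"),
                          group_col = "group", fdr = 0.1) {
  miss <- setdiff(measures, names(metrics))
  if (length(miss) > 0) {
    abort(sprintf("Unknown measure(s): %s.", paste(miss, collapse = ", ")))
  }
  ga <- metrics[[group_col]] == groups[1]
  gb <- metrics[[group_col]] == groups[2]
  if (sum(ga) < 1 || sum(gb) < 1) abort("Both groups must be non-empty.")
  rows <- purrr::map_dfr(measures, function(ms) {
    a <- metrics[[ms]][ga]
    b <- metrics[[ms]][gb]
    mw <- mann_whitney_exact(a, b)
    tibble(
      measure = ms,
      median_a = median(a), min_a = min(a), max_a = max(a),
      median_b = median(b), min_b = min(b), max_b = max(b),
      U = mw$U, p = mw$p
    )
  })
  rows$q <- bh_adjust(rows$p)
  rows$significant <- rows$q < fdr
  rows
}

#' Correlate along-tract measures with laterality indices
#'
#' Spearman rank correlation for every (measure, LI) pair, joined by
#' subject id, with Benjamini-Hochberg adjustment over the whole grid.
#'
#' @param metrics wide per-subject tibble with a `subject_id` column.
#' @param li_table tibble (subject_id, lobe, li).
#' @param measures measure column names in `metrics`.
#' @param lobes lobe labels to use (default: all in `li_table`).
#' @param method p-value method passed to [spearman_rho()]; the
#'   t-approximation is the reporting default.
#' @param fdr FDR level for the significance flag (default 0.1).
#' @return tibble: measure, lobe, rho, p, q, significant, n.
#' @export
correlate_with_li <- function(metrics, li_table, measures,
                              lobes = unique(li_table$lobe),
                              method = "tapprox", fdr = 0.1) {
  miss <- setdiff(measures, names(metrics))
  if (length(miss) > 0) {
    abort(sprintf("Unknown measure(s): %s.", paste(miss, collapse = ", ")))
  }
  li_wide <- li_table |>
    dplyr::filter(.data$lobe %in% lobes) |>
    tidyr::pivot_wider(
      id_cols = "subject_id", names_from = "lobe", values_from = "li"
    )
  joined <- dplyr::inner_join(metrics, li_wide, by = "subject_id")
  if (nrow(joined) < 3) abort("Fewer than 3 subjects shared between tables.")
  if (nrow(joined) < nrow(metrics)) {
    abort("Subject ids do not match between metrics and LI tables.")
  }
  rows <- purrr::map_dfr(measures, function(ms) {
    purrr::map_dfr(lobes, function(lb) {
      sp <- spearman_rho(joined[[ms]], joined[[lb]], method = method)
      tibble(
        measure = ms, lobe = lb, rho = sp$rho, p = sp$p,
        method = sp$method, n = nrow(joined)
      )
    })
  })
  rows$q <- bh_adjust(rows$p)
  rows$significant <- !is.na(rows$q) & rows$q < fdr
  rows
}
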