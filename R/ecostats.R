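check_community <- function(p) {
  if (length(p) == 0L || all(p == 0)) {
    stop("community vector has no positive entries", call. = FALSE)
  }
  if (any(p < 0)) stop("negative abundance", call. = FALSE)
  p
}

#' Shannon-Wiener diversity index
#'
#' `H = -sum p_i log(p_i)` with natural log by default; zero-abundance
#' species contribute 0. Non-normalised vectors are normalised internally.
#'
#' @param p Non-negative abundance vector.
#' @param base Logarithm base (default `exp(1)`; use 2 for bits).
#' @return The index value.
#' @examples
#' shannon(rep(1, 4))  # log(4)
#' @export
shannon <- function(p, base = exp(1)) {
  p <- check_community(p)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Simpson diversity index
#'
#' `D = 1 - sum p_i^2` (probability two random draws are different species).
#'
#' @inheritParams shannon
#' @return The index value in `[0, 1 - 1/S]`.
#' @examples
#' simpson(rep(1, 4))  # 0.75
#' @export
simpson <- function(p) {
  p <- check_community(p)
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and
#' `F2` are the numbers of singleton and doubleton species. The corrected
#' form is always used so the estimator is defined when no doubletons are
#' observed.
#'
#' @param counts Non-negative integer count vector.
#' @return The estimated species richness.
#' @examples
#' chao1(c(1, 1, 2, 5, 10))  # 5 + 2*1/(2*1) = 6
#' @export
chao1 <- function(counts) {
  check_community(counts)
  if (any(counts != round(counts))) {
    stop("chao1 requires integer counts", call. = FALSE)
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Bray-Curtis dissimilarity
#'
#' `sum |x_i - y_i| / sum (x_i + y_i)` over a shared species universe.
#'
#' @param x,y Non-negative abundance vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(1, 2), c(2, 2))  # 1/7
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("negative abundance", call. = FALSE)
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all-zero", call. = FALSE)
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis distance matrix from an abundance table
#'
#' @param tbl Tibble with a `species` column and one numeric column per
#'   sample (as from [abundance_table()]).
#' @return Symmetric matrix of Bray-Curtis dissimilarities.
#' @export
bray_curtis_matrix <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "species")])
  ns <- ncol(m)
  D <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      D[i, j] <- D[j, i] <- bray_curtis(m[, i], m[, j])
    }
  }
  D
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total sum
#' of squared distances `SS_T = (1/n) sum_{i<j} d_ij^2` into within-group
#' (`SS_W`, summed per group with its own size) and between-group parts, and
#' refers the pseudo-F statistic to a permutation distribution of group
#' labels. The p-value uses `(1 + exceedances) / (1 + n_permutations)` so it
#' is never zero; with a fixed seed the result is reproducible bit for bit.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param groups Group labels (length `nrow(d)`); at least 2 groups with at
#'   least 2 members each.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return Object of class `permanova`: list with `F`, `R2`, `p`, `df`,
#'   `SS` and the call parameters.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  groups <- as.factor(groups)
  a <- nlevels(groups)
  if (a < 2L || any(table(groups) < 2L)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  d2 <- d^2
  ss_t <- sum(d2[upper.tri(d2)]) / n
  fstat <- function(g) {
    ss_w <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ss_b <- ss_t - ss_w
    (ss_b / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- fstat(groups)
  ss_w_obs <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    ss_w_obs <- ss_w_obs + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) /
      length(idx)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  exceed <- sum(vapply(seq_len(n_permutations), function(i) {
    fstat(sample(groups)) >= f_obs
  }, logical(1)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(
    F = f_obs,
    R2 = (ss_t - ss_w_obs) / ss_t,
    p = (1 + exceed) / (1 + n_permutations),
    df = c(between = a - 1L, within = n - a),
    SS = c(total = ss_t, within = ss_w_obs, between = ss_t - ss_w_obs),
    n_permutations = n_permutations, seed = seed),
    class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.4f (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
              x$F, x$df[1], x$df[2], x$R2, x$p, x$n_permutations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PERMANOVA fit
#'
#' @param x A `permanova` object.
#' @param ... Unused.
#' @return One row per term (`between`, `within`, `total`) with `df`,
#'   `sum_of_squares`, `statistic`, `p.value`.
#' @export
tidy.permanova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within", "total"),
    df = c(x$df[["between"]], x$df[["within"]],
           x$df[["between"]] + x$df[["within"]]),
    sum_of_squares = c(x$SS[["between"]], x$SS[["within"]], x$SS[["total"]]),
    statistic = c(x$F, NA, NA),
    p.value = c(x$p, NA, NA))
}

#' @rdname tidy.permanova
#' @export
glance.permanova <- function(x, ...) {
  tibble::tibble(statistic = x$F, r.squared = x$R2, p.value = x$p,
                 n_permutations = x$n_permutations)
}

#' Alpha-diversity table for a set of profiles
#'
#' Shannon and Simpson from relative abundances, Chao1 from read counts.
#'
#' @param profiles List of `abundance_profile` objects.
#' @return Tibble `sample_id`, `n_species`, `shannon`, `simpson`, `chao1`.
#' @export
alpha_diversity <- function(profiles) {
  purrr::map_dfr(profiles, function(p) {
    tibble::tibble(sample_id = attr(p, "sample_id"),
                   n_species = nrow(p),
                   shannon = shannon(p$relative_abundance),
                   simpson = simpson(p$relative_abundance),
                   chao1 = chao1(p$reads))
  })
}
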