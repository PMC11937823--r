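# Alpha diversity, Bray-Curtis dissimilarity, principal-coordinates
# ordination, UPGMA clustering and permutational MANOVA.

#' Alpha diversity (richness and Shannon)
#'
#' Richness is the number of features with a positive count; Shannon is the
#' entropy of the relative-abundance profile, `-sum(p * log(p, base))` over
#' features with `p > 0`. The log base defaults to 2 (bits); natural log is
#' selectable. Computed via [vegan::diversity()] with a change of base.
#'
#' @param x An [AmpliconExperiment-class] or a count matrix.
#' @param base Logarithm base, `2` (default) or `exp(1)`.
#' @return `data.frame` with `sample_id`, `richness`, `shannon`.
#' @export
alphaDiversity <- function(x, base = 2) {
  m <- if (methods::is(x, "AmpliconExperiment")) counts(x) else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  h <- vegan::diversity(t(m), index = "shannon") / log(base)
  data.frame(sample_id = colnames(m),
             richness = unname(colSums(m > 0)),
             shannon = unname(h),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))`, computed with
#' [vegan::vegdist()]. Entries lie in \[0, 1\]; identical columns give 0 and
#' disjoint supports give 1.
#'
#' @param x An [AmpliconExperiment-class] or a count matrix with at least
#'   two samples.
#' @return A [stats::dist] object labelled by sample ids.
#' @export
brayCurtisMatrix <- function(x) {
  m <- if (methods::is(x, "AmpliconExperiment")) counts(x) else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least two samples")
  zero <- colSums(m) == 0
  if (sum(zero) >= 2L)
    stop("dissimilarity undefined between all-zero samples: ",
         paste(colnames(m)[zero], collapse = ", "))
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: the squared distances are
#' double-centered, eigendecomposed, and coordinates are eigenvectors
#' scaled by the square roots of the positive eigenvalues (via
#' [stats::cmdscale()]). Negative eigenvalues -- which arise because
#' Bray-Curtis is not Euclidean -- are reported with a warning rather than
#' silently dropped; a Cailliez correction is available.
#'
#' @param d A `dist` or symmetric matrix with zero diagonal.
#' @param correction `"none"` (default) or `"cailliez"` to make the matrix
#'   Euclidean before decomposition.
#' @return List of class `"pcoaOrdination"` with `coordinates` (samples x
#'   axes, axes ordered by decreasing eigenvalue), `eigenvalues` (all of
#'   them, including any negative), and `proportionExplained` (over the
#'   positive eigenvalues).
#' @export
pcoaOrdination <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  labs <- attr(d, "Labels")
  if (all(d == 0)) {
    coords <- matrix(0, n, 1L, dimnames = list(labs, "Axis1"))
    out <- list(coordinates = coords, eigenvalues = rep(0, n),
                proportionExplained = NA_real_)
    class(out) <- "pcoaOrdination"
    return(out)
  }
  fit <- withCallingHandlers(
    stats::cmdscale(d, k = n - 1L, eig = TRUE,
                    add = correction == "cailliez"),
    # cmdscale warns when fewer than k eigenvalues are positive; we report
    # the full spectrum ourselves, so that warning is redundant here
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  coords <- fit$points
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  rownames(coords) <- labs
  eig <- fit$eig
  if (any(eig < -1e-8))
    warning("negative eigenvalues present (non-Euclidean distances); ",
            "reported in 'eigenvalues'")
  pos <- eig[eig > 1e-12]
  prop <- rep(NA_real_, ncol(coords))
  prop[seq_along(pos)] <- pos / sum(pos)
  out <- list(coordinates = coords, eigenvalues = eig,
              proportionExplained = prop[seq_len(ncol(coords))])
  class(out) <- "pcoaOrdination"
  out
}

#' @export
print.pcoaOrdination <- function(x, ...) {
  cat("PCoA ordination:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes\n")
  pe <- x$proportionExplained
  if (!all(is.na(pe)))
    cat("  proportion explained (first axes):",
        paste(sprintf("%.1f%%", 100 * utils::head(pe[!is.na(pe)], 3L)),
              collapse = ", "), "\n")
  invisible(x)
}

#' UPGMA clustering of samples
#'
#' Agglomerates the closest pair of clusters at each step, with
#' average linkage weighted by cluster sizes (so every original sample
#' contributes equally), placing the merge node at half the merge distance.
#' Distance ties are broken by the lexicographically smallest pair of
#' cluster representatives (the alphabetically first leaf of each cluster),
#' making the tree deterministic. The result is a rooted ultrametric
#' binary tree.
#'
#' @param d A `dist` or symmetric distance matrix over at least two
#'   samples.
#' @return An [ape::read.tree()] `"phylo"` object; export with
#'   [ape::write.tree()].
#' @export
upgmaTree <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(m)
  if (n < 2L) stop("need at least two samples")
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("S", seq_len(n))
  # cluster state: newick fragment, height, size, representative leaf
  nwk <- labs
  height <- rep(0, n)
  size <- rep(1L, n)
  rep_leaf <- labs
  active <- seq_len(n)
  D <- m
  while (length(active) > 1L) {
    best <- NULL
    best_d <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        i <- active[a]; j <- active[b]
        dij <- D[i, j]
        lo <- min(rep_leaf[i], rep_leaf[j])
        hi <- max(rep_leaf[i], rep_leaf[j])
        if (dij < best_d - 1e-12 ||
            (abs(dij - best_d) <= 1e-12 && !is.null(best) &&
             (lo < best$lo || (lo == best$lo && hi < best$hi)))) {
          best <- list(i = i, j = j, lo = lo, hi = hi)
          best_d <- dij
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best_d / 2
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)",
                       nwk[i], h - height[i], nwk[j], h - height[j])
    # size-weighted average linkage to every other active cluster
    others <- setdiff(active, c(i, j))
    for (k in others) {
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    nwk[i] <- new_nwk
    height[i] <- h
    size[i] <- size[i] + size[j]
    rep_leaf[i] <- min(rep_leaf[i], rep_leaf[j])
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(nwk[active], ";"))
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components and forms the pseudo-F statistic
#' `F = (SSA / (a - 1)) / (SSW / (n - a))`. Significance comes from
#' permuting group labels; the p-value uses the `(1 + b) / (1 + m)`
#' estimator (the observed statistic counts as one permutation), so p can
#' never be exactly zero. With `exact = TRUE` all `n!` label permutations
#' are enumerated instead (feasible for `n <= 8`) and
#' `p = #\{F_perm >= F_obs\} / n!`.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param groups Group labels, one per sample, in the order of the distance
#'   matrix labels (or a named vector matching them).
#' @param nPermutations Number of random permutations (default 999).
#' @param seed Integer seed; required unless `exact = TRUE`.
#' @param exact Enumerate all permutations instead of sampling.
#' @return List of class `"permanovaResult"` with `pseudoF`, `R2`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permanovaTest <- function(d, groups, nPermutations = 999, seed = NULL,
                          exact = FALSE) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(m)
  labs <- rownames(m)
  if (!is.null(names(groups)) && !is.null(labs))
    groups <- groups[labs]
  groups <- as.factor(groups)
  if (length(groups) != n) stop("one group label per sample is required")
  a <- nlevels(droplevels(groups))
  if (a < 2L) stop("need at least two groups")
  if (a >= n) stop("need residual degrees of freedom (more samples than groups)")
  d2 <- m^2
  sst <- sum(d2) / (2 * n)
  ssw_of <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1L)
        s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_of <- function(g) {
    ssw <- ssw_of(g)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)
  r2 <- 1 - ssw_of(groups) / sst
  if (exact) {
    perms <- .allPermutations(n)
    f_perm <- vapply(perms, function(idx) f_of(groups[idx]), numeric(1L))
    p <- sum(f_perm >= f_obs - 1e-12) / length(perms)
    nperm <- length(perms)
  } else {
    if (is.null(seed)) stop("'seed' is required for random permutations")
    b <- withSeed(seed, {
      sum(vapply(seq_len(nPermutations), function(i) {
        f_of(groups[sample.int(n)]) >= f_obs - 1e-12
      }, logical(1L)))
    })
    p <- (1 + b) / (1 + nPermutations)
    nperm <- nPermutations
  }
  out <- list(pseudoF = f_obs, R2 = r2, p_value = p,
              n_permutations = nperm, seed = seed)
  class(out) <- "permanovaResult"
  out
}

#' @export
print.permanovaResult <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$pseudoF, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

# all permutations of seq_len(n); guarded for small n only
.allPermutations <- function(n) {
  if (n > 8L) stop("exact enumeration limited to n <= 8")
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
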