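#' Identity-by-state genetic distance matrix
#'
#' For each sample pair, over sites where both genotypes are called:
#' allele share `= sum(2 - |g_i - g_j|) / (2 m)` with `m` the shared
#' called-site count; distance `d = 1 - share` (the 1-IBS convention of
#' the usual SNP toolkits). Apply [mask_low_gq()] first to honour a
#' genotype-quality cutoff.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param samples Optional sample ids (default all, >= 2).
#' @return A list of class `ibs_dist`: `d` (symmetric matrix in `[0,1]`,
#'   zero diagonal), `n_sites` (per-pair shared called sites).
#' @export
ibs_distance <- function(gm, samples = NULL) {
  d <- if (is.null(samples)) gm$dosage else gm$dosage[, samples, drop = FALSE]
  ns <- ncol(d)
  if (ns < 2) abort("need at least two samples")
  called <- !is.na(d)
  dz <- d
  dz[!called] <- 0L
  # pairwise sum over shared sites of |g_i - g_j| via the identity
  # |x - y| = x + y - 2*min(x, y); min over dosages decomposes into
  # indicator products: min(x,y) = [x>=1][y>=1] + [x==2][y==2]
  ge1 <- (dz >= 1L) & called
  eq2 <- (dz == 2L) & called
  m_pair <- crossprod(called)                       # shared called sites
  sum_x <- crossprod(called, dz)                    # sum of g_i over shared
  abs_diff <- sum_x + t(sum_x) - 2 * (crossprod(ge1) + crossprod(eq2))
  if (any(m_pair[upper.tri(m_pair)] == 0)) {
    idx <- which(m_pair == 0 & upper.tri(m_pair), arr.ind = TRUE)[1, ]
    abort(paste0("no shared called sites for pair ",
                 colnames(d)[idx[1]], " / ", colnames(d)[idx[2]]))
  }
  dist_m <- abs_diff / (2 * m_pair)
  diag(dist_m) <- 0
  dimnames(dist_m) <- list(colnames(d), colnames(d))
  structure(list(d = dist_m, n_sites = m_pair), class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat(sprintf("<ibs_dist> %d samples, mean distance %.4f\n",
              nrow(x$d), mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Tidy an IBS distance matrix into pair rows
#' @param x An `ibs_dist`.
#' @param ... Unused.
#' @method tidy ibs_dist
#' @export
tidy.ibs_dist <- function(x, ...) {
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(sample_a = rownames(x$d)[ut[, 1]],
         sample_b = colnames(x$d)[ut[, 2]],
         distance = x$d[ut],
         n_sites = x$n_sites[ut])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); exact on additive distance
#' matrices. Negative branch lengths (possible on noisy input) are
#' clamped to zero in the returned tree; the raw lengths are kept in
#' `raw_edge_length`.
#'
#' @param d An [ibs_distance()] result, `dist` object or symmetric
#'   matrix.
#' @return A list of class `nj_result`: `tree` (an \pkg{ape} `phylo`,
#'   clamped), `raw_edge_length` (numeric, pre-clamp).
#' @export
nj_tree <- function(d) {
  m <- if (inherits(d, "ibs_dist")) d$d else as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) abort("distance matrix must be symmetric")
  if (nrow(m) < 3) abort("neighbor-joining needs at least three samples")
  tree <- ape::nj(stats::as.dist(m))
  raw <- tree$edge.length
  tree$edge.length <- pmax(raw, 0)
  structure(list(tree = tree, raw_edge_length = raw), class = "nj_result")
}

#' Serialize a tree as Newick
#'
#' Labels containing whitespace or Newick metacharacters are
#' single-quoted (placeholder substitution keeps the serializer from
#' mangling them); [from_newick()] reverses the quoting, so the pair
#' round-trips topology, branch lengths and labels exactly.
#'
#' @param tree An `nj_result` or `phylo` object.
#' @param path Optional file to write; when `NULL` the string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
to_newick <- function(tree, path = NULL) {
  phy <- if (inherits(tree, "nj_result")) tree$tree else tree
  labs <- phy$tip.label
  needs_quote <- grepl("[][\\s():;,']", labs, perl = TRUE)
  token <- sprintf("invasweepTIP%06d", seq_along(labs))
  phy$tip.label <- ifelse(needs_quote, token, labs)
  s <- ape::write.tree(phy)
  for (i in which(needs_quote)) {
    quoted <- paste0("'", gsub("'", "''", labs[i]), "'")
    s <- sub(token[i], quoted, s, fixed = TRUE)
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Parse a Newick string or file
#'
#' @param x A Newick string, or a path to a file holding one.
#' @return An \pkg{ape} `phylo` object with quoting undone.
#' @export
from_newick <- function(x) {
  phy <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  phy$tip.label <- gsub("''", "'", sub("^'(.*)'$", "\\1", phy$tip.label))
  phy
}

#' @export
print.nj_result <- function(x, ...) {
  cat(sprintf("<nj_result> unrooted neighbor-joining tree, %d tips\n",
              length(x$tree$tip.label)))
  if (any(x$raw_edge_length < 0)) {
    cat(sprintf("  %d negative branch(es) clamped to 0\n",
                sum(x$raw_edge_length < 0)))
  }
  invisible(x)
}

#' Principal component analysis of a genotype matrix
#'
#' Patterson-style normalisation: missing dosages are mean-imputed, each
#' site is centred by `2 p` and scaled by `sqrt(2 p (1 - p))` with `p`
#' the observed alternate frequency; sites fixed in the sample are
#' dropped. Components come from the eigendecomposition of the sample
#' covariance of the normalised matrix.
#'
#' @param gm A filtered [genotype_matrix()] (apply [mask_low_gq()] first
#'   to honour a genotype-quality cutoff).
#' @param samples Optional sample ids (default all).
#' @param k Number of components (`<= samples - 1`).
#' @return A list of class `pca_result`: `coordinates` (tibble `sample`,
#'   `PC1..PCk`), `eigenvalues` (all, descending), `var_explained`
#'   (fractions for the returned components), `n_sites_used`.
#' @export
pca_genotypes <- function(gm, samples = NULL, k = 2) {
  d <- if (is.null(samples)) gm$dosage else gm$dosage[, samples, drop = FALSE]
  ns <- ncol(d)
  if (ns < 2) abort("need at least two samples")
  if (k > ns - 1) abort("k must be at most samples - 1")
  called <- !is.na(d)
  n_called <- rowSums(called)
  p_hat <- rowSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1))
  keep <- n_called > 0 & p_hat > 0 & p_hat < 1
  d <- d[keep, , drop = FALSE]
  p <- p_hat[keep]
  x <- d
  x[is.na(x)] <- 0
  x <- x + (!called[keep, , drop = FALSE]) * (2 * p)   # mean imputation
  z <- (x - 2 * p) / sqrt(2 * p * (1 - p))
  cov_s <- crossprod(z) / nrow(z)
  eig <- eigen(cov_s, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(vals[seq_len(k)]), `*`)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(
    coordinates = bind_cols(tibble(sample = colnames(d)), as_tibble(coords)),
    eigenvalues = vals,
    var_explained = vals[seq_len(k)] / sum(vals),
    n_sites_used = nrow(z)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$coordinates) - 1
  cat(sprintf(
    "<pca_result> %d samples, %d sites; top %d PCs explain %.1f%% of variance\n",
    nrow(x$coordinates), x$n_sites_used, k, 100 * sum(x$var_explained)))
  invisible(x)
}

#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) x$coordinates

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_samples = nrow(x$coordinates),
         n_sites_used = x$n_sites_used,
         total_variance = sum(x$eigenvalues),
         pc1_var_explained = x$var_explained[1],
         pc2_var_explained = if (length(x$var_explained) > 1)
           x$var_explained[2] else NA_real_)
}
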