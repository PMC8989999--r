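#' Proportion of differing sites between two aligned sequences
#'
#' Pairwise deletion: alignment columns with a gap (`-` or `.`) in either
#' sequence are excluded; the p-distance is mismatches over the remaining
#' compared sites.
#'
#' @param seq_a,seq_b aligned sequences of equal length, as single strings
#'   or character vectors of residues.
#' @return the mismatch proportion, with attribute `n_sites` (compared
#'   sites).
#' @export
p_distance <- function(seq_a, seq_b) {
  if (length(seq_a) == 1L && nchar(seq_a) > 1L) seq_a <- strsplit(seq_a, "")[[1]]
  if (length(seq_b) == 1L && nchar(seq_b) > 1L) seq_b <- strsplit(seq_b, "")[[1]]
  if (length(seq_a) != length(seq_b)) stop("sequences have unequal length")
  gap <- seq_a %in% c("-", ".") | seq_b %in% c("-", ".")
  a <- seq_a[!gap]; b <- seq_b[!gap]
  if (!length(a)) stop("zero comparable sites (all gap columns)")
  p <- mean(a != b)
  attr(p, "n_sites") <- length(a)
  p
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed mismatch proportion p to expected substitutions
#' per site under the a-state equal-rates model:
#' `d = -((a-1)/a) * log(1 - (a/(a-1)) * p)`. At or beyond the model's
#' saturation point `p >= (a-1)/a` the distance is undefined; such pairs
#' are assigned the cap distance and flagged rather than raising an error,
#' so large divergent alignments still yield a tree.
#'
#' @param p mismatch proportion(s) in \[0, 1\].
#' @param alphabet_size 4 (nucleotide) or 20 (protein).
#' @param cap distance assigned to saturated pairs; default 5 subs/site.
#' @return corrected distance(s), with logical attribute `saturated`.
#' @export
jc_distance <- function(p, alphabet_size = 20, cap = 5) {
  a <- alphabet_size
  if (!a %in% c(4, 20)) stop("`alphabet_size` must be 4 or 20")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  sat <- p >= (a - 1) / a
  d <- numeric(length(p))
  d[!sat] <- -((a - 1) / a) * log(1 - (a / (a - 1)) * p[!sat])
  d[sat] <- cap
  attr(d, "saturated") <- sat
  d
}

#' Jukes-Cantor corrected distance matrix from an alignment
#'
#' All pairwise p-distances (pairwise deletion) corrected with
#' [jc_distance()].
#'
#' @param aln character matrix of aligned residues, rownames are taxa.
#' @param alphabet_size 4 or 20.
#' @param cap saturation cap passed to [jc_distance()].
#' @return a list of class `"jc_dist"`: `labels`, `d` (symmetric numeric
#'   matrix, zero diagonal), `saturated` (logical matrix).
#' @export
jc_distance_matrix <- function(aln, alphabet_size = 20, cap = 5) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- p_distance(aln[i, ], aln[j, ])
    dd <- jc_distance(as.numeric(p), alphabet_size, cap)
    d[i, j] <- d[j, i] <- as.numeric(dd)
    sat[i, j] <- sat[j, i] <- attr(dd, "saturated")
  }
  structure(list(labels = rownames(aln), d = d, saturated = sat),
            class = "jc_dist")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: at each step the pair (i, j)
#' minimizing `Q(i,j) = (n-2) d(i,j) - R_i - R_j` (R = row sums over
#' active nodes) is joined; branch lengths follow the standard formulas.
#' Ties are broken by lowest (row, column) index. Negative branch lengths
#' are clamped to 0 with the deficit shifted to the sister branch, so the
#' joined pair's path length is preserved.
#'
#' @param dm symmetric numeric distance matrix with labelled rows/columns
#'   and zero diagonal (or a `"jc_dist"` object), `>= 3` taxa.
#' @return an unrooted [ape::phylo] tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "jc_dist")) dm <- dm$d
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("need >= 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(dm < 0)) stop("negative distances")
  labels <- rownames(dm)
  ## node ids: tips 1..n, internals n+1, n+2, ... (ape convention: root
  ## id n+1 assigned to the last join)
  active <- seq_len(n)          # current node id per active row of dm
  next_internal <- n + 2L       # reserve n+1 for the final 3-way node
  edges <- matrix(0L, 0, 2)
  elen <- numeric(0)
  D <- dm
  while (length(active) > 3) {
    m <- length(active)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    ## tie-break: lowest (row, col) with row < col in index order
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
    li <- 0.5 * D[bi, bj] + (R[bi] - R[bj]) / (2 * (m - 2))
    lj <- D[bi, bj] - li
    ## clamp negatives, shift deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, active[bi]), c(u, active[bj]))
    elen <- c(elen, li, lj)
    dnew <- 0.5 * (D[bi, ] + D[bj, ] - D[bi, bj])
    keep <- setdiff(seq_len(m), c(bi, bj))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    active <- c(active[keep], u)
  }
  ## final 3-way join at the (unrooted) central node, id n+1
  u <- n + 1L
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  ll <- pmax(c(l1, l2, l3), 0)
  edges <- rbind(edges, c(u, active[1]), c(u, active[2]), c(u, active[3]))
  elen <- c(elen, ll)
  nnode <- next_internal - n - 1L
  tr <- list(edge = edges, edge.length = unname(elen), tip.label = labels,
             Nnode = nnode)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Felsenstein bootstrap: alignment columns are resampled with replacement
#' `n_reps` times; each replicate's JC distance matrix and NJ tree are
#' recomputed, and the support of each internal edge of the reference tree
#' is the number of replicates whose tree contains the same bipartition
#' (0..n_reps scale). Seeded and reproducible.
#'
#' @param aln character matrix of aligned residues, `>= 4` taxa.
#' @param n_reps number of bootstrap replicates, `>= 1`; 100 is the
#'   conventional default.
#' @param seed integer RNG seed.
#' @param alphabet_size 4 or 20.
#' @param cap saturation cap for [jc_distance()].
#' @return the reference NJ tree with `node.label` holding supports on
#'   internal nodes (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1,
                              alphabet_size = 20, cap = 5) {
  stopifnot(is.matrix(aln))
  if (ncol(aln) < 1) stop("alignment has no columns")
  if (nrow(aln) < 4) stop("need >= 4 taxa for informative supports")
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  ref <- neighbor_joining(jc_distance_matrix(aln, alphabet_size, cap))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    reps[[b]] <- neighbor_joining(
      jc_distance_matrix(aln[, cols, drop = FALSE], alphabet_size, cap))
  }
  supp <- ape::prop.clades(ref, reps, rooted = FALSE)
  supp[is.na(supp)] <- 0L
  ## the basal node's "bipartition" is the trivial full-taxon split
  lbl <- as.character(supp)
  lbl[1] <- ""
  ref$node.label <- lbl
  ref
}

#' Write a tree as Newick text
#'
#' Branch lengths to 6 decimals; bootstrap supports (if present) are
#' encoded as internal node labels.
#'
#' @param tree an [ape::phylo] tree.
#' @param path file path, or `NULL` to return the Newick string.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a tree from Newick text or a file
#'
#' @param text Newick string, or `NULL` to read from `path`.
#' @param path file path.
#' @return an [ape::phylo] tree (internal node labels preserved).
#' @export
read_newick <- function(text = NULL, path = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text)
        else ape::read.tree(file = path)
  if (is.null(tr)) stop("malformed Newick text")
  tr
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm a `"jc_dist"` object or a labelled symmetric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  if (inherits(dm, "jc_dist")) dm <- dm$d
  n <- nrow(dm)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i)
               paste(formatC(rownames(dm)[i], width = -10),
                     paste(sprintf("%.6f", dm[i, ]), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
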