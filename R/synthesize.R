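#' Channel specification for the population simulator
#'
#' Describes one fluorescence reporter channel of a simulated population:
#' the probability that a cell has the reporter switched ON, the
#' distribution family of ON intensities, and the residual emission of OFF
#' cells. The Cad reporter is right-skewed (lognormal ON intensities with a
#' sizeable OFF subpopulation), while the Gad and Adi reporters are
#' Gaussian-like.
#'
#' @param name channel label, e.g. `"gad"`, `"adi"`, `"cad"`.
#' @param on_fraction probability in \[0,1\] that a cell is ON.
#' @param family distribution family of ON intensities, `"lognormal"` or
#'   `"normal"`.
#' @param loc location parameter: mean for `"normal"`, log-space mean for
#'   `"lognormal"`.
#' @param scale spread parameter (same convention as `loc`), `>= 0`.
#' @param off_level mean intensity emitted by OFF cells, `>= 0`.
#' @return an object of class `"channel_spec"`.
#' @export
channel_spec <- function(name, on_fraction = 1, family = c("lognormal", "normal"),
                         loc = 6, scale = 0.5, off_level = 0) {
  family <- match.arg(family)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  if (on_fraction < 0 || on_fraction > 1)
    stop("`on_fraction` must be in [0, 1]")
  if (scale < 0) stop("`scale` must be >= 0")
  if (off_level < 0) stop("`off_level` must be >= 0")
  structure(list(name = name, on_fraction = on_fraction, family = family,
                 loc = loc, scale = scale, off_level = off_level),
            class = "channel_spec")
}

#' Population specification for the three-colour cell simulator
#'
#' Bundles the channel marginals with the latent inter-channel correlation
#' matrix, the additive spectral bleed-through matrix, and a per-field
#' Gaussian background model. The bleed matrix entry `bleed[receiver, donor]`
#' is the fraction of the donor channel's true signal added to the receiver
#' channel (the study's GFP <- CFP bleed-through is one such entry).
#'
#' @param channels list of [channel_spec()] objects.
#' @param correlation symmetric positive semi-definite matrix of latent
#'   inter-channel correlations with unit diagonal; default identity.
#' @param bleed square crosstalk matrix, zero diagonal; entry (r, d) is the
#'   fraction of donor d's true signal added to receiver r.
#' @param background_mean,background_sd per-field background model
#'   (intensity units); one background value is drawn per field and channel.
#' @param n_fields number of fields of view.
#' @param cells_per_field cells per field.
#' @param condition,time_min free-form condition label and time point
#'   carried into the output table.
#' @param seed integer RNG seed.
#' @return an object of class `"population_spec"`.
#' @export
population_spec <- function(channels, correlation = NULL, bleed = NULL,
                            background_mean = 0, background_sd = 0,
                            n_fields = 1, cells_per_field = 100,
                            condition = "cond", time_min = 0, seed = 1) {
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  if (!length(channels) || !all(vapply(channels, inherits, TRUE, "channel_spec")))
    stop("`channels` must be a list of channel_spec objects")
  k <- length(channels)
  nm <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("channel names must be unique")
  if (is.null(correlation)) correlation <- diag(k)
  correlation <- as.matrix(correlation)
  if (!identical(dim(correlation), c(k, k)))
    stop("`correlation` must be ", k, "x", k)
  if (max(abs(correlation - t(correlation))) > 1e-8)
    stop("`correlation` must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-8)
    stop("`correlation` must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("`correlation` is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  if (is.null(bleed)) bleed <- matrix(0, k, k)
  bleed <- as.matrix(bleed)
  if (!identical(dim(bleed), c(k, k))) stop("`bleed` must be ", k, "x", k)
  if (any(diag(bleed) != 0)) stop("`bleed` diagonal must be zero")
  if (any(bleed < 0)) stop("`bleed` entries must be >= 0")
  if (background_mean < 0 || background_sd < 0)
    stop("background parameters must be >= 0")
  if (n_fields < 1 || cells_per_field < 1) stop("counts must be >= 1")
  structure(list(channels = channels, correlation = correlation, bleed = bleed,
                 background_mean = background_mean, background_sd = background_sd,
                 n_fields = n_fields, cells_per_field = cells_per_field,
                 condition = condition, time_min = time_min,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Simulate a three-colour reporter cell population
#'
#' Draws one record per cell. Latent inter-channel correlation is imposed by
#' a Gaussian copula: correlated standard normals are transformed through
#' `pnorm` and then through each channel's marginal quantile function, so the
#' stated marginal families are preserved exactly. Each channel's ON/OFF
#' state is an independent Bernoulli draw with its `on_fraction`. The
#' measured intensity of a channel is
#' `true + sum(bleed[channel, donor] * true_donor) + field background`;
#' both the latent true value and the measured value are retained so that
#' downstream estimators (crosstalk fit, noise, ON fraction) can be
#' validated against the generating parameters.
#'
#' @param spec a [population_spec()].
#' @return a data frame with one row per cell: `cell_id`, `field`,
#'   `condition`, `time_min`, per-channel `<name>_true`, `<name>_on` and
#'   `<name>_raw` columns, and nominal shape columns (`length_um`,
#'   `width_um`, `area_um2`). Identical spec (including seed) gives an
#'   identical table.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  k <- length(spec$channels)
  nm <- vapply(spec$channels, `[[`, "", "name")
  n <- spec$n_fields * spec$cells_per_field
  field <- rep(seq_len(spec$n_fields), each = spec$cells_per_field)

  ## per-field, per-channel background (one draw each)
  bg_field <- matrix(stats::rnorm(spec$n_fields * k, spec$background_mean,
                                  spec$background_sd),
                     nrow = spec$n_fields, ncol = k)

  ## Gaussian copula: correlated N(0,1) -> uniforms -> marginals
  ee <- eigen(spec$correlation, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), k)
  z <- matrix(stats::rnorm(n * k), n, k) %*% t(L)
  u <- stats::pnorm(z)

  true_mat <- matrix(0, n, k)
  on_mat <- matrix(FALSE, n, k)
  for (j in seq_len(k)) {
    ch <- spec$channels[[j]]
    on <- stats::runif(n) < ch$on_fraction
    onval <- switch(ch$family,
      lognormal = stats::qlnorm(u[, j], meanlog = ch$loc, sdlog = ch$scale),
      normal    = stats::qnorm(u[, j], mean = ch$loc, sd = ch$scale))
    true_mat[, j] <- ifelse(on, onval, ch$off_level)
    on_mat[, j] <- on
  }
  meas_mat <- true_mat + true_mat %*% t(spec$bleed) + bg_field[field, , drop = FALSE]

  len <- stats::runif(n, 1.5, 4.5)
  wid <- stats::runif(n, 0.5, 0.9)
  out <- data.frame(cell_id = seq_len(n), field = field,
                    condition = spec$condition, time_min = spec$time_min,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    out[[paste0(nm[j], "_true")]] <- true_mat[, j]
    out[[paste0(nm[j], "_on")]] <- on_mat[, j]
    out[[paste0(nm[j], "_raw")]] <- meas_mat[, j]
  }
  out$length_um <- len
  out$width_um <- wid
  out$area_um2 <- len * wid
  out
}

#' Simulate a presence/absence table of regulator homologs
#'
#' Emulates a deposited homolog table: every row is a species carrying the
#' anchor component (e.g. the antiporter CadB), and each regulator column is
#' an independent Bernoulli draw with its conditional presence probability
#' given the anchor.
#'
#' @param n_species number of species rows.
#' @param anchor_component name of the anchor component (flag always 1).
#' @param regulator_probs named numeric vector, regulator -> conditional
#'   presence probability in \[0,1\].
#' @param seed integer RNG seed.
#' @return a data frame: `species_id`, one column per anchor/regulator with
#'   0/1 flags, of class `c("presence_matrix", "data.frame")` with
#'   attribute `anchor`.
#' @export
simulate_presence_table <- function(n_species, anchor_component,
                                    regulator_probs, seed = 1) {
  if (n_species < 1) stop("`n_species` must be >= 1")
  if (is.null(names(regulator_probs)) || any(!nzchar(names(regulator_probs))))
    stop("`regulator_probs` must be a named vector")
  if (any(regulator_probs < 0 | regulator_probs > 1))
    stop("probabilities must be in [0, 1]")
  set.seed(seed)
  out <- data.frame(species_id = sprintf("sp%05d", seq_len(n_species)),
                    stringsAsFactors = FALSE)
  out[[anchor_component]] <- 1L
  for (reg in names(regulator_probs))
    out[[reg]] <- stats::rbinom(n_species, 1L, regulator_probs[[reg]])
  attr(out, "anchor") <- anchor_component
  class(out) <- c("presence_matrix", "data.frame")
  out
}

#' Evolve an ungapped alignment along a tree
#'
#' Simulates i.i.d. columns down a tree under the a-state equal-rates
#' substitution model (the model whose distance correction is the
#' generalized Jukes-Cantor formula). Along a branch of length `d` expected
#' substitutions/site, the probability that the end state differs from the
#' start state is `p = ((a-1)/a) * (1 - exp(-(a/(a-1)) * d))`, and a
#' substituted site takes one of the other `a - 1` states uniformly.
#'
#' @param tree an [ape::phylo] tree with branch lengths in expected
#'   substitutions/site and at least 3 leaves.
#' @param seq_length number of alignment columns, `>= 1`.
#' @param alphabet `"protein"` (20 states) or `"nucleotide"` (4 states).
#' @param seed integer RNG seed.
#' @return a character matrix of residues, one row per leaf (rownames are
#'   the tip labels), all rows equal length, no gaps.
#' @export
evolve_alignment <- function(tree, seq_length,
                             alphabet = c("protein", "nucleotide"), seed = 1) {
  alphabet <- match.arg(alphabet)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("`tree` must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (length(tree$tip.label) < 3) stop("`tree` must have >= 3 leaves")
  if (seq_length < 1) stop("`seq_length` must be >= 1")
  states <- if (alphabet == "protein")
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] else c("A", "C", "G", "T")
  a <- length(states)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(a, seq_length, replace = TRUE)
  ## parent-before-child edge order
  tr <- stats::reorder(tree, "postorder")
  ord <- rev(seq_len(nrow(tr$edge)))
  for (e in ord) {
    par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]; d <- tr$edge.length[e]
    p <- ((a - 1) / a) * (1 - exp(-(a / (a - 1)) * d))
    s <- seqs[[par]]
    hit <- stats::runif(seq_length) < p
    if (any(hit)) {
      ## uniform over the a-1 other states
      shift <- sample.int(a - 1L, sum(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% a) + 1L
    }
    seqs[[chd]] <- s
  }
  aln <- t(vapply(seq_len(ntip), function(i) states[seqs[[i]]],
                  character(seq_length)))
  rownames(aln) <- tree$tip.label
  aln
}

#' Write an alignment matrix as FASTA
#'
#' @param aln character matrix of residues, rownames are sequence names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1, paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an aligned FASTA file into a character matrix
#'
#' All sequences must have equal length (it is an alignment, gaps allowed).
#'
#' @param path FASTA file path.
#' @return character matrix of residues, rownames are sequence names.
#' @export
read_alignment_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  idx <- cumsum(hdr)
  nm <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, "", collapse = "")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths; not an alignment")
  if (lens[1] == 0L) stop("zero-length alignment")
  aln <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(aln) <- nm
  aln
}
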