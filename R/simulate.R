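#' Configuration for the paired multi-omics simulator
#'
#' The simulator plants two independent (near-orthogonal) partitions in
#' the same cells: a "type" partition and a "state" partition. Each
#' partition modulates its own disjoint block of genes and of peaks, so
#' both partitions are recoverable from the fused data but from
#' different feature subsets -- the data regime the multiple-clusterings
#' stage is designed to exploit.
#'
#' @param n_cells,n_genes,n_peaks dataset dimensions.
#' @param n_types,n_states number of clusters in each planted partition
#'   (both >= 2); labels are assigned independently.
#' @param type_effect,state_effect log-scale (RNA mean) and logit-scale
#'   (peak accessibility) shift applied to a cluster's own feature
#'   block. Defaults (2.0 and 1.5) give strong type separation and
#'   clear but weaker state separation, as is typical of cell-type vs
#'   cell-state structure.
#' @param type_block_frac,state_block_frac fraction of genes (and of
#'   peaks) reserved for type-specific and state-specific blocks; the
#'   blocks are disjoint.
#' @param dropout_pi zero-inflation probability of the RNA counts.
#' @param theta negative binomial dispersion (variance `mu + mu^2/theta`).
#' @param peak_open_p baseline peak accessibility probability.
#' @param lib_sd standard deviation of the per-cell log-normal library
#'   size factor.
#' @param seed integer RNG seed; the whole draw is deterministic in it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 300, n_genes = 200, n_peaks = 300,
                       n_types = 4, n_states = 2,
                       type_effect = 2.0, state_effect = 1.5,
                       type_block_frac = 0.30, state_block_frac = 0.15,
                       dropout_pi = 0.3, theta = 2, peak_open_p = 0.1,
                       lib_sd = 0.2, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_types >= 2, cfg$n_states >= 2, cfg$n_cells >= 2,
            cfg$type_effect >= 0, cfg$state_effect >= 0,
            cfg$dropout_pi >= 0, cfg$dropout_pi < 1, cfg$theta > 0,
            cfg$peak_open_p > 0, cfg$peak_open_p < 1)
  n_block_feats <- function(n) floor(n * cfg$type_block_frac) +
    floor(n * cfg$state_block_frac)
  if (n_block_feats(cfg$n_genes) > cfg$n_genes ||
      n_block_feats(cfg$n_peaks) > cfg$n_peaks ||
      floor(cfg$n_genes * cfg$type_block_frac / cfg$n_types) < 1 ||
      floor(cfg$n_peaks * cfg$type_block_frac / cfg$n_types) < 1)
    stop("config error: feature blocks exceed n_genes/n_peaks")
  class(cfg) <- "sim_config"
  cfg
}

# index blocks: per-cluster disjoint feature blocks for a partition
block_index <- function(n_feat, frac, n_clust, offset) {
  per <- floor(n_feat * frac / n_clust)
  lapply(seq_len(n_clust), function(j) offset + (j - 1L) * per + seq_len(per))
}

#' Draw zero-inflated negative binomial samples
#'
#' With probability `pi` an observation is a structural zero; otherwise
#' it is a negative binomial draw with mean `mu` and dispersion `theta`
#' (variance `mu + mu^2/theta`).
#'
#' @param n number of draws.
#' @param mu mean vector (recycled), `mu >= 0`.
#' @param theta dispersion, `> 0`.
#' @param pi zero-inflation probability in `[0, 1]`.
#' @return Integer vector of length `n`.
#' @export
zinb_sample <- function(n, mu, theta, pi) {
  stopifnot(all(mu >= 0), theta > 0, pi >= 0, pi <= 1)
  x <- stats::rnbinom(n, size = theta, mu = mu)
  drop <- stats::rbinom(n, 1, pi)
  x * (1 - drop)
}

#' Simulate a paired RNA/ATAC dataset with planted orthogonal partitions
#'
#' RNA counts are ZINB draws around cell-specific means: a per-gene
#' baseline, shifted up by `type_effect` (log scale) on the cell's own
#' type gene block and by `state_effect` on its state gene block, times
#' a log-normal library size factor. Peaks are Bernoulli draws with the
#' baseline `peak_open_p` shifted on the logit scale on the analogous
#' peak blocks. Type and state labels are drawn independently.
#'
#' @param cfg a [sim_config].
#' @return A `sim_output` list with fields `omics` ([omics_pair]),
#'   `true_rna_mean` (pre-dropout NB means), `type_labels`,
#'   `state_labels` (integer vectors in `1..n_types` / `1..n_states`).
#' @export
simulate_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  N <- cfg$n_cells
  type <- sample.int(cfg$n_types, N, replace = TRUE)
  state <- sample.int(cfg$n_states, N, replace = TRUE)

  gene_type_blocks <- block_index(cfg$n_genes, cfg$type_block_frac, cfg$n_types, 0L)
  gene_state_blocks <- block_index(cfg$n_genes, cfg$state_block_frac, cfg$n_states,
                                   max(unlist(gene_type_blocks)))
  peak_type_blocks <- block_index(cfg$n_peaks, cfg$type_block_frac, cfg$n_types, 0L)
  peak_state_blocks <- block_index(cfg$n_peaks, cfg$state_block_frac, cfg$n_states,
                                   max(unlist(peak_type_blocks)))

  base_mu <- stats::runif(cfg$n_genes, 0.2, 2)
  logmu <- matrix(log(base_mu), N, cfg$n_genes, byrow = TRUE)
  for (j in seq_len(cfg$n_types))
    logmu[type == j, gene_type_blocks[[j]]] <-
      logmu[type == j, gene_type_blocks[[j]]] + cfg$type_effect
  for (j in seq_len(cfg$n_states))
    logmu[state == j, gene_state_blocks[[j]]] <-
      logmu[state == j, gene_state_blocks[[j]]] + cfg$state_effect
  libf <- exp(stats::rnorm(N, 0, cfg$lib_sd))
  mu <- exp(logmu) * libf
  rna <- matrix(zinb_sample(length(mu), as.vector(mu), cfg$theta, cfg$dropout_pi),
                N, cfg$n_genes)

  logit_p <- matrix(stats::qlogis(cfg$peak_open_p), N, cfg$n_peaks)
  for (j in seq_len(cfg$n_types))
    logit_p[type == j, peak_type_blocks[[j]]] <-
      logit_p[type == j, peak_type_blocks[[j]]] + cfg$type_effect
  for (j in seq_len(cfg$n_states))
    logit_p[state == j, peak_state_blocks[[j]]] <-
      logit_p[state == j, peak_state_blocks[[j]]] + cfg$state_effect
  atac <- matrix(stats::rbinom(length(logit_p), 1, stats::plogis(as.vector(logit_p))),
                 N, cfg$n_peaks)

  cells <- sprintf("cell%0*d", nchar(N), seq_len(N))
  rownames(rna) <- rownames(atac) <- cells
  colnames(rna) <- paste0("gene", seq_len(cfg$n_genes))
  colnames(atac) <- paste0("peak", seq_len(cfg$n_peaks))

  structure(list(omics = omics_pair(rna, atac),
                 true_rna_mean = mu,
                 type_labels = type, state_labels = state,
                 config = cfg),
            class = "sim_output")
}

#' Write a simulated dataset to disk
#'
#' Writes the paired matrices in the standard dialects plus a labels TSV
#' (`cell_id`, `type`, `state`) and a JSON sidecar of the configuration.
#'
#' @param sim a `sim_output` from [simulate_pair].
#' @param dir output directory.
#' @param format passed to [write_omics_pair].
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir, format = c("mtx", "dense_delim")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_pair(sim$omics, dir, format)
  utils::write.table(
    data.frame(cell_id = sim$omics$cell_ids, type = sim$type_labels,
               state = sim$state_labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
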