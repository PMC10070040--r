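#' Derive a stable per-stage seed from the global seed
#'
#' One global seed fans out to per-stage seeds via a small multiplicative
#' hash, so stages can be rerun independently yet reproducibly. Result
#' stays below 2^31.
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

build_cfg <- function(ctor, overrides) {
  overrides <- overrides[intersect(names(overrides), names(formals(ctor)))]
  do.call(ctor, overrides)
}

#' Run the full pipeline: simulate/read, fuse, impute, cluster, evaluate
#'
#' Executes the stages in order, writing each stage's outputs under
#' `out_dir` and an atomic `manifest.json` (resolved config, seed,
#' package version, input hashes, output paths, per-stage wall time)
#' at the end. The config is a YAML/JSON file (or an equivalent list)
#' with optional blocks `simulate` (simulator settings) or `input`
#' (`rna`, `atac`, `format`), `fusion`, `multiclust`, and top-level
#' `seed` and `out_dir`. Block keys mirror the constructor arguments of
#' [sim_config], [fusion_config] and [multiclust_config]. A single
#' global seed fans out to per-stage seeds via [derive_seed]; block
#' seeds override.
#'
#' @param config path to a YAML/JSON config file, or a list.
#' @param out_dir output directory (overrides the config entry).
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfgl <- if (is.character(config)) read_config(config) else config
  seed <- cfgl$seed %||% 1L
  out_dir <- out_dir %||% cfgl$out_dir %||% stop("config error: out_dir required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package = "scMultiClust",
                   version = as.character(utils::packageVersion("scMultiClust")),
                   seed = seed, config = cfgl, outputs = list(), timings = list(),
                   input_hashes = list())
  tic <- function() proc.time()[["elapsed"]]
  stage_t <- function(t0) round(tic() - t0, 3)

  # ---- inputs ----
  t0 <- tic()
  truth <- NULL
  if (!is.null(cfgl$simulate)) {
    sc <- build_cfg(sim_config, utils::modifyList(
      list(seed = derive_seed(seed, "simulate")), as.list(cfgl$simulate)))
    sim <- simulate_pair(sc)
    pair <- sim$omics
    truth <- list(type = sim$type_labels, state = sim$state_labels)
    write_sim_output(sim, file.path(out_dir, "data"))
    manifest$outputs$data <- file.path(out_dir, "data")
    say("simulate: %d cells, %d genes, %d peaks", sc$n_cells, sc$n_genes, sc$n_peaks)
  } else if (!is.null(cfgl$input)) {
    pair <- read_omics_pair(cfgl$input$rna, cfgl$input$atac,
                            cfgl$input$format %||% "mtx")
    for (f in c(cfgl$input$rna, cfgl$input$atac))
      if (file.exists(f) && !dir.exists(f))
        manifest$input_hashes[[f]] <- unname(tools::md5sum(f))
    say("read: %d cells", length(pair$cell_ids))
  } else stop("config error: need a 'simulate' or 'input' block")
  manifest$timings$input <- stage_t(t0)

  # ---- stage 1: fusion ----
  t0 <- tic()
  fc <- build_cfg(fusion_config, utils::modifyList(
    list(seed = derive_seed(seed, "fuse")), as.list(cfgl$fusion %||% list())))
  st1 <- train_stage1(pair, fc)
  utils::write.table(cbind(cell_id = pair$cell_ids, as.data.frame(st1$latents$ZI)),
                     file.path(out_dir, "ZI.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(st1$loss_history, file.path(out_dir, "stage1_loss.csv"),
                   row.names = FALSE)
  imp <- impute(st1)
  utils::write.table(imp$imputed_rna, file.path(out_dir, "imputed_rna.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  manifest$outputs$ZI <- file.path(out_dir, "ZI.tsv")
  manifest$outputs$stage1_loss <- file.path(out_dir, "stage1_loss.csv")
  manifest$timings$fuse <- stage_t(t0)
  say("fuse: final L1 = %.4f", utils::tail(st1$loss_history$total, 1))

  # ---- stage 2: multiple clusterings ----
  t0 <- tic()
  mc <- build_cfg(multiclust_config, utils::modifyList(
    list(seed = derive_seed(seed, "multicluster")),
    as.list(cfgl$multiclust %||% list())))
  st2 <- train_stage2(st1$latents$ZI, mc)
  lab <- data.frame(cell_id = pair$cell_ids)
  for (l in seq_len(mc$L)) lab[[paste0("clustering", l)]] <- st2$clusters$labels[[l]]
  utils::write.table(lab, file.path(out_dir, "clusterings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(st2$loss_history, file.path(out_dir, "stage2_loss.csv"),
                   row.names = FALSE)
  manifest$outputs$clusterings <- file.path(out_dir, "clusterings.tsv")
  manifest$timings$multicluster <- stage_t(t0)
  say("multicluster: L=%d", mc$L)

  # ---- evaluation ----
  t0 <- tic()
  ev <- list()
  km <- kmeans_single_clustering(st1$latents$ZI,
                                 k = mc$cluster_counts[1],
                                 seed = derive_seed(seed, "evaluate"))
  if (!is.null(truth)) {
    ev$kmeans_nmi_type <- nmi(km, truth$type)
    ev$kmeans_ari_type <- ari(km, truth$type)
    for (l in seq_len(mc$L)) {
      ev[[paste0("C", l, "_nmi_type")]] <- nmi(st2$clusters$labels[[l]], truth$type)
      ev[[paste0("C", l, "_nmi_state")]] <- nmi(st2$clusters$labels[[l]], truth$state)
    }
  }
  if (mc$L >= 2) {
    dv <- diversity(st2$clusters$labels[[1]], st2$clusters$labels[[2]])
    ev$diversity_one_minus_nmi <- unname(dv["one_minus_nmi"])
    ev$diversity_one_minus_ji <- unname(dv["one_minus_ji"])
  }
  for (l in seq_len(mc$L)) {
    lab_l <- st2$clusters$labels[[l]]
    degenerate <- length(unique(lab_l)) < 2   # collapsed clustering: no SC/DI
    ev[[paste0("C", l, "_silhouette")]] <- if (degenerate) NA_real_ else
      silhouette_score(st2$headset$heads[[l]], lab_l)
    ev[[paste0("C", l, "_dunn")]] <- if (degenerate) NA_real_ else
      dunn_index(st2$headset$heads[[l]], lab_l)
  }
  utils::write.csv(as.data.frame(ev), file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  manifest$outputs$metrics <- file.path(out_dir, "metrics.csv")
  manifest$timings$evaluate <- stage_t(t0)

  # ---- manifest (atomic write) ----
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
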