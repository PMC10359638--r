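#' Run the end-to-end depletion analysis on synthetic data
#'
#' Drives the full analysis order on a paired untreated/depleted synthetic
#' experiment: simulate, balance, expected/OE, saddle, APA, insulation and
#' its aggregate change, per-loop strengths and log2 fold changes,
#' responsive-loop classification, loop-length GSEA of the strengthened
#' loops, and gene-category enrichment inside the responsive set. Every
#' stage writes its artifact into `out_dir` and is recorded in a JSON
#' manifest (parameters, seeds, per-file md5 checksums, stage status);
#' rerunning with the same config is bit-identical for deterministic
#' stages.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param n_perm Permutation count used by the permutation stages
#'   (default 500, scaled for a desk run).
#' @return Invisibly, a list with the in-memory results of every stage
#'   plus the `manifest`.
#' @export
run_depletion_pipeline <- function(config = sim_config(), out_dir,
                                   n_perm = 500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    parameters = list(seed = config$seed, bin_size = config$bin_size,
                      depth = config$depth, n_perm = n_perm),
    stages = list(), files = list())
  res <- list()
  note <- function(stage, status) {
    manifest$stages[[stage]] <<- status
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", status)
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest$files[[name]] <<- unname(tools::md5sum(path))
    path
  }
  run_stage <- function(stage, fn) {
    ok <- tryCatch({ fn(); TRUE },
                   error = function(e) { note(stage, paste("failed:",
                                                           conditionMessage(e)))
                     FALSE })
    if (ok) note(stage, "ok")
    ok
  }
  ok <- run_stage("simulate", function() {
    res$sim <<- simulate_perturbation_experiment(config)
    emit("loops_planted.bedpe", function(p) write_loops(res$sim$loops, p))
    emit("genes.tsv", function(p) write_genes(res$sim$genes, p))
  })
  if (!ok) {
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
    return(invisible(list(manifest = manifest)))
  }
  run_stage("balance", function() {
    res$oe <<- list()
    for (cond in c("before", "after")) {
      mats <- res$sim[[cond]]$mats
      mats <- lapply(mats, filter_min_distance, min_sep = 20000)
      bal <- lapply(mats, ice_balance)
      res$oe[[cond]] <<- lapply(bal, oe_transform)
      res[[paste0("balanced_", cond)]] <<- bal
    }
  })
  run_stage("expected", function() {
    expected <- dplyr::bind_rows(lapply(res$balanced_before,
                                        expected_by_distance))
    emit("expected_before.tsv", function(p) {
      utils::write.table(expected, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  })
  run_stage("saddle", function() {
    e1 <- dplyr::bind_rows(lapply(res$oe$before, compartment_eigenvector))
    active <- track_from_values(
      config$genome, config$bin_size,
      ifelse(res$sim$truth$structure$compartments$label > 0, 1, 0))
    e1 <- orient_eigenvector(e1, active)
    res$saddle <<- lapply(res$oe, function(mats) saddle(mats, e1))
    emit("saddle_before.tsv", function(p) write_saddle(res$saddle$before, p))
    emit("saddle_after.tsv", function(p) write_saddle(res$saddle$after, p))
  })
  run_stage("pileup", function() {
    res$apa <<- lapply(res$oe, function(mats) apa(mats, res$sim$loops))
    emit("apa_before.tsv", function(p) write_pileup(res$apa$before, p))
    emit("apa_after.tsv", function(p) write_pileup(res$apa$after, p))
  })
  run_stage("insulation", function() {
    win <- 10 * config$bin_size
    res$insulation <<- lapply(c(before = "before", after = "after"),
                              function(cond) {
      dplyr::bind_rows(lapply(res[[paste0("balanced_", cond)]],
                              insulation_score, window = win))
    })
    emit("insulation_before.bedgraph", function(p) {
      ins <- res$insulation$before
      tr <- new_signal_track(
        tibble::tibble(chrom = ins$chrom, bin = ins$bin, start = ins$start,
                       value = ifelse(is.finite(ins$insulation),
                                      ins$insulation, 0)),
        config$bin_size)
      write_track(tr, p, config$genome)
    })
  })
  run_stage("loops", function() {
    sb <- loop_strength(res$oe$before, res$sim$loops)$strength
    sa <- loop_strength(res$oe$after, res$sim$loops)$strength
    res$loop_stats <<- dplyr::mutate(
      res$sim$loops, strength_obs_before = sb, strength_obs_after = sa,
      lfc = log2(sa / sb))
    emit("loop_strength.tsv", function(p) {
      utils::write.table(res$loop_stats, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  })
  run_stage("classify", function() {
    res$classes <<- classify_responsive_loops(
      res$sim$loops, res$sim$tf_peaks, res$sim$down_cohesin_peaks,
      res$sim$atac_peaks, genome = config$genome)
    emit("responsive_loops.bedpe", function(p) {
      write_loops(res$classes$responsive, p)
    })
    emit("less_responsive_loops.bedpe", function(p) {
      write_loops(res$classes$less_responsive, p)
    })
  })
  run_stage("permtest", function() {
    gained <- !is.na(res$loop_stats$lfc) & res$loop_stats$lfc > 0.2
    if (!any(gained) || all(gained)) stop("degenerate gained-loop set")
    res$gsea <<- length_rank_gsea(res$loop_stats, gained, n_perm = n_perm,
                                  seed = config$seed)
    res$gene_enrich <<- gene_category_enrichment(
      res$classes$responsive, res$sim$genes, config$genome,
      n_perm = n_perm, seed = config$seed)
    emit("gsea.json", function(p) {
      jsonlite::write_json(as.list(tidy(res$gsea)), p, auto_unbox = TRUE,
                           digits = NA)
    })
    emit("gene_category_enrichment.tsv", function(p) {
      utils::write.table(res$gene_enrich, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  })
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}

# build a signal_track on the contact-map binning from a per-bin vector
track_from_values <- function(genome, bin_size, values) {
  tr <- empty_track(genome, bin_size)
  stopifnot(length(values) == nrow(tr))
  tr$value <- values
  tr
}
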