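default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = "cucumap_run",
    stages = list(simulate = TRUE, map = TRUE, integrate = TRUE,
                  annotate = TRUE, anchor = TRUE, report = TRUE),
    truth = list(),
    crosses = list(
      css_f2 = list(kind = "F2", n_individuals = 92),
      csh_ril = list(kind = "RIL", n_individuals = 77),
      css_ril = list(kind = "RIL", n_individuals = 148)
    ),
    sequences = list(est_params = list(), primer_params = list()),
    mapping = list(lod_threshold = 5, rf_threshold = 0.35,
                   map_function = "kosambi"),
    integration = list(bin_width = 1, exclusions = NULL,
                       reference_map = "css_f2"),
    annotation = list(n_bootstrap = 200),
    anchoring = list(max_product = 2000, max_mismatch = 0)
  )
}

validate_config <- function(config) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    abort(paste0("unknown configuration keys: ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(def, config)
  bad_stage <- setdiff(names(cfg$stages), names(def$stages))
  if (length(bad_stage)) {
    abort(paste0("unknown stage toggles: ", paste(bad_stage, collapse = ", ")))
  }
  cfg
}

#' Run the full synthetic-cross analysis pipeline
#'
#' Orchestrates the stages in dependency order: simulate (truth genome,
#' populations, sequences), map (a component map per population), integrate
#' (bin-mapping consensus), annotate (RGH classification, clusters, NB
#' phylogeny, EST support), anchor (in silico PCR, scaffold anchoring,
#' colinearity) and report (summary tables). All randomness derives from
#' `config$seed`, so re-running with the same configuration reproduces
#' byte-identical artifacts.
#'
#' @param config A configuration list (missing entries filled from
#'   defaults) or the path of a YAML file holding one. Unknown keys are
#'   rejected. See `cucumap:::default_pipeline_config()` for the schema.
#' @return Invisibly, a list with `status` (0 on success), `manifest`
#'   (tibble `file`, `md5`, `bytes`) and the in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, enabled, fun) {
    if (!enabled) return(invisible(NULL))
    message("[cucumap] stage: ", name)
    tryCatch(fun(), error = function(e) {
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)))
    })
  }
  wt <- function(x, f) readr::write_tsv(as_tibble(x), file.path(out_dir, f))

  stage("simulate", cfg$stages$simulate, function() {
    tcfg <- utils::modifyList(list(seed = cfg$seed), cfg$truth)
    truth <- simulate_truth(do.call(sim_truth_config, tcfg))
    pops <- list()
    for (k in seq_along(cfg$crosses)) {
      cr <- cfg$crosses[[k]]
      cr$seed <- cr$seed %||% child_seed(cfg$seed, names(cfg$crosses)[k])
      pops[[names(cfg$crosses)[k]]] <- simulate_population(
        truth, do.call(cross_design, cr))
    }
    seqs <- simulate_sequences(truth, cfg$sequences$est_params,
                               cfg$sequences$primer_params,
                               seed = child_seed(cfg$seed, "sequences"))
    res$truth <<- truth
    res$populations <<- pops
    res$sequences <<- seqs
    write_fixture_bundle(truth, pops, seqs, file.path(out_dir, "fixtures"))
  })

  stage("map", cfg$stages$map, function() {
    maps <- lapply(names(res$populations), function(nm) {
      m <- build_component_map(
        res$populations[[nm]],
        lod_threshold = cfg$mapping$lod_threshold,
        rf_threshold = cfg$mapping$rf_threshold,
        map_function = cfg$mapping$map_function, name = nm)
      align_linkage_groups(m, attr(res$populations[[nm]], "truth_map"))
    })
    names(maps) <- names(res$populations)
    res$maps <<- maps
    for (nm in names(maps)) wt(maps[[nm]], paste0("map_", nm, ".tsv"))
  })

  stage("integrate", cfg$stages$integrate, function() {
    ms <- res$truth$markers[, c("id", "scaffold_id")] |>
      rename(marker = "id", scaffold = "scaffold_id")
    cons <- integrate_maps(
      res$maps, geno = res$populations, marker_scaffold = ms,
      bin_width = cfg$integration$bin_width,
      exclusions = cfg$integration$exclusions,
      reference_map = cfg$integration$reference_map,
      map_function = cfg$mapping$map_function)
    res$consensus <<- cons
    wt(cons, "consensus_map.tsv")
    wt(attr(cons, "bins"), "bins.tsv")
    wt(attr(cons, "conflicts"), "conflicts.tsv")
    pairs <- combn(names(res$maps), 2, simplify = FALSE)
    conc <- bind_rows(lapply(pairs, function(p) {
      order_concordance(res$maps[[p[1]]], res$maps[[p[2]]]) |>
        mutate(map_x = p[1], map_y = p[2])
    }))
    res$concordance <<- conc
    wt(conc, "concordance.tsv")
  })

  stage("annotate", cfg$stages$annotate, function() {
    ann <- classify_rgh(res$sequences$annotations)
    genes <- res$truth$rgh_genes
    cl <- detect_clusters(genes)
    res$classified <<- ann
    res$clusters <<- cl
    res$cluster_stats <<- cluster_stats(cl)
    tree <- nj_tree(res$sequences$nb_truth,
                    n_bootstrap = cfg$annotation$n_bootstrap,
                    seed = child_seed(cfg$seed, "bootstrap"))
    res$tree <<- tree
    gene_seq <- tibble(
      gene = genes$id,
      sequence = vapply(seq_len(nrow(genes)), function(i) {
        substr(as.character(res$sequences$scaffolds[[genes$scaffold_id[i]]]),
               genes$start_bp[i], genes$end_bp[i])
      }, character(1)))
    res$est_support <<- est_support_table(gene_seq, res$sequences$ests)
    wt(ann, "rgh_classified.tsv")
    wt(cl, "rgh_clusters.tsv")
    wt(res$cluster_stats, "rgh_cluster_stats.tsv")
    wt(res$est_support[, c("gene", "supported", "hit_count")],
       "rgh_est_support.tsv")
    ape::write.tree(tree, file.path(out_dir, "nb_tree.nwk"))
    # clusters as BED (0-based half-open)
    bed <- res$clusters |>
      group_by(.data$cluster, .data$seqname) |>
      summarise(start = min(.data$start_bp) - 1L, end = max(.data$end_bp),
                .groups = "drop")
    readr::write_tsv(bed[, c("seqname", "start", "end", "cluster")],
                     file.path(out_dir, "rgh_clusters.bed"),
                     col_names = FALSE)
  })

  stage("anchor", cfg$stages$anchor, function() {
    pcr <- insilico_pcr(res$sequences$primers, res$sequences$scaffolds,
                        max_product = cfg$anchoring$max_product,
                        max_mismatch = cfg$anchoring$max_mismatch)
    uniq <- pcr$amplicons[pcr$amplicons$marker %in%
                            pcr$labels$marker[pcr$labels$label == "unique"], ]
    lens <- res$truth$scaffolds[, c("id", "length_bp")] |>
      rename(scaffold_id = "id")
    anch <- anchor_scaffolds(res$consensus, uniq, lens,
                             genome_bp = sum(res$truth$chromosomes$length_bp))
    col <- colinearity_check(res$consensus, uniq)
    res$pcr <<- pcr
    res$anchors <<- anch
    res$colinearity <<- col
    wt(pcr$amplicons, "amplicons.tsv")
    wt(pcr$labels, "pcr_labels.tsv")
    wt(anch, "anchor_report.tsv")
    wt(attr(anch, "totals"), "anchor_totals.tsv")
    wt(col, "colinearity.tsv")
  })

  stage("report", cfg$stages$report, function() {
    if (!is.null(res$consensus)) {
      wt(summarize_map(res$consensus, res$anchors), "summary_map.tsv")
    } else {
      message("[cucumap] report: consensus missing, map summary skipped")
    }
    if (!is.null(res$classified)) {
      wt(summarize_classes(res$classified), "summary_classes.tsv")
      wt(summarize_clusters(res$clusters, res$classified),
         "summary_clusters.tsv")
    } else {
      message("[cucumap] report: annotation missing, class summary skipped")
    }
  })

  files <- sort(list.files(out_dir, recursive = TRUE))
  paths <- file.path(out_dir, files)
  manifest <- tibble(file = files, md5 = unname(tools::md5sum(paths)),
                     bytes = file.size(paths))
  invisible(c(list(status = 0L, manifest = manifest), res))
}
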