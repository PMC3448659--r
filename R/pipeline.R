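# End-to-end orchestration: simulate/ingest -> JSD scores -> metafeatures ->
# MST-kNN clustering -> quality metrics -> permutation FDR -> marker reports,
# with a manifest that makes every artifact reproducible.

#' Default pipeline configuration
#'
#' @return A list of defaults; see [run_pipeline()] for the fields.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "mstknn_out",
    simulate = NULL,
    expression = NULL,
    annotation = NULL,
    control_samples = NULL,
    severe_samples = NULL,
    ops = c("ratio", "sum", "diff", "prod"),
    use_metafeatures = TRUE,
    markers = NULL,
    min_size = 3L,
    q = NULL,
    c2_policy = "pmax",
    fdr = list(marker = NULL, thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
               n_perm = 200L)
  )
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: load (or simulate) the expression matrix and annotation; compute
#' per-sample JSD progression scores when control and severe groups are
#' available; expand metafeatures; assemble the analysis matrix with marker
#' rows; cluster with the modified MST-kNN algorithm; score homogeneity and
#' separation; estimate the permutation FDR for one marker; write per-marker
#' cluster reports, the robust-marker table and a JSON run manifest. All
#' outputs are deterministic for a fixed config and seed.
#'
#' @param config A configuration list or path to a YAML file. Recognized
#'   fields: `seed`, `output_dir`, either `simulate` (arguments of
#'   [planted_expression()] plus optional `marker_block`/`marker_rho`) or
#'   `expression`/`annotation` paths, `control_samples`/`severe_samples`,
#'   `ops`, `use_metafeatures`, `markers`, `min_size`, `q`, `c2_policy`, and
#'   `fdr` (`marker`, `thresholds`, `n_perm`).
#' @return Invisibly, a list with the clustering, quality metrics, FDR table,
#'   reports and the manifest. On stage failure a `FAILED` file naming the
#'   stage is left in the output directory and the error is rethrown.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  # validate inputs before writing anything
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$expression)) stop("config needs either 'simulate' or 'expression'")
    if (!file.exists(cfg$expression)) stop("missing input path: ", cfg$expression)
    if (!is.null(cfg$annotation) && !file.exists(cfg$annotation)) {
      stop("missing input path: ", cfg$annotation)
    }
  }
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage), file.path(out, "FAILED"))
    stop(e)
  }
  tryCatch({
    annotation <- NULL
    marker_tab <- list()
    if (!is.null(cfg$simulate)) {
      stage <- "simulate"
      sim_args <- cfg$simulate[intersect(names(cfg$simulate),
                                         names(formals(planted_expression)))]
      sim_args$seed <- sim_args$seed %||% cfg$seed
      sim <- do.call(planted_expression, sim_args)
      X <- sim$X
      write_expression(X, file.path(out, "expression.tsv"))
      mb <- cfg$simulate$marker_block %||% 1L
      mr <- cfg$simulate$marker_rho %||% 0.9
      marker_tab[["sim"]] <- planted_marker(sim, mb, mr, seed = cfg$seed + 1L)
      truth <- sim$labels
    } else {
      stage <- "ingest"
      X <- read_expression(cfg$expression)
      truth <- NULL
      if (!is.null(cfg$annotation)) {
        annotation <- read_annotation(cfg$annotation)
        ann <- annotation[match(colnames(X), annotation$sample_id), ]
        for (mk in c("mmse", "nft", "braak")) {
          v <- ann[[mk]]
          if (!anyNA(v)) {
            names(v) <- colnames(X)
            marker_tab[[mk]] <- as.numeric(v)
            names(marker_tab[[mk]]) <- colnames(X)
          }
        }
      }
    }

    stage <- "jsd"
    ctrl <- cfg$control_samples
    sev <- cfg$severe_samples
    if (is.null(ctrl) && !is.null(annotation)) {
      ctrl <- annotation$sample_id[!is.na(annotation$group) & annotation$group == "control"]
    }
    if (is.null(sev) && !is.null(annotation)) {
      sev <- annotation$sample_id[!is.na(annotation$group) & annotation$group == "severe"]
    }
    if (length(ctrl) && length(sev)) {
      js <- jsd_scores(X, ctrl, sev)
      v <- js$jsd_control; names(v) <- js$sample_id
      marker_tab[["jsd_control"]] <- v
      v <- js$jsd_severe; names(v) <- js$sample_id
      marker_tab[["jsd_severe"]] <- v
      utils::write.table(
        data.frame(sample_id = js$sample_id,
                   jsd_control = sprintf("%.6f", js$jsd_control),
                   jsd_severe = sprintf("%.6f", js$jsd_severe)),
        file.path(out, "jsd_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(cfg$markers)) marker_tab <- marker_tab[intersect(names(marker_tab), cfg$markers)]

    stage <- "metafeatures"
    meta <- if (isTRUE(cfg$use_metafeatures)) generate_metafeatures(X, cfg$ops) else NULL

    stage <- "assemble"
    A <- assemble_analysis_matrix(X, meta,
                                  if (length(marker_tab)) marker_tab else NULL)

    stage <- "cluster"
    clustering <- mstknn(A, min_size = cfg$min_size, q = cfg$q,
                         c2_policy = cfg$c2_policy)
    write_clusters(clustering, file.path(out, "clusters.tsv"))
    write_forest_edges(clustering$forest, file.path(out, "forest_edges.tsv"))

    stage <- "evaluate"
    n_clusters <- length(unique(clustering$assignment))
    h <- unname(homogeneity(A, clustering))
    s <- if (n_clusters >= 2L) unname(separation(A, clustering)) else NA_real_

    stage <- "fdr"
    fdr_tab <- NULL
    fdr_marker <- cfg$fdr$marker %||% (if (length(marker_tab)) names(marker_tab)[1L])
    if (!is.null(fdr_marker) && fdr_marker %in% names(marker_tab)) {
      target <- if (is.null(meta)) X else meta
      fdr_tab <- permutation_fdr(target, marker_tab[[fdr_marker]][colnames(target)],
                                 thresholds = cfg$fdr$thresholds,
                                 n_perm = cfg$fdr$n_perm, seed = cfg$seed)
      ft <- fdr_tab
      ft$mean_null_count <- sprintf("%.6f", ft$mean_null_count)
      ft$fdr <- sprintf("%.6f", ft$fdr)
      utils::write.table(ft, file.path(out, "fdr.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    stage <- "report"
    reports <- list()
    if (length(marker_tab)) {
      members <- find_marker_clusters(clustering, names(marker_tab))
      for (mk in names(marker_tab)) {
        reports[[mk]] <- rank_members(members[[mk]], A,
                                      marker_tab[[mk]][colnames(A)],
                                      marker_id = mk)
        write_marker_report(reports[[mk]],
                            file.path(out, paste0("marker_", mk, ".tsv")))
      }
      if (length(reports) >= 2L) {
        rb <- robust_markers(reports)
        con <- file(file.path(out, "robust_markers.tsv"), open = "wb")
        writeLines("probe_id\tmarkers", con)
        if (length(rb)) {
          writeLines(paste(names(rb),
                           vapply(rb, paste, character(1L), collapse = ","),
                           sep = "\t"), con)
        }
        close(con)
      }
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("mstknn")),
      config = cfg[order(names(cfg))],
      n_features_input = nrow(X),
      n_metafeatures = if (is.null(meta)) 0L else nrow(meta),
      n_nodes_clustered = length(clustering$assignment),
      q_used = clustering$q_used,
      n_clusters = n_clusters,
      h_avg = round(h, 6),
      s_avg = if (is.na(s)) NULL else round(s, 6)
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(list(clustering = clustering, h_avg = h, s_avg = s,
                   fdr = fdr_tab, reports = reports, manifest = manifest,
                   truth = truth, analysis_matrix = A))
  }, error = on_fail)
}
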