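config_schema <- function() {
  list(
    seed = NULL,
    outdir = NULL,
    paths = list(protein_matrix = NULL, peptides = NULL, design = NULL,
                 id_map = NULL, pathways = NULL, disease_set = NULL,
                 ppi_edges = NULL),
    data = list(protein_matrix = NULL, peptides = NULL, design = NULL,
                id_map = NULL, pathways = NULL, disease_set = NULL,
                ppi_edges = NULL),
    quantify = list(n_top = 3, aggregate = "mean"),
    preprocess = list(max_missing_fraction = 0.5, digits = 6),
    network = list(power = NULL, min_cluster_size = 30, deep_split = 3,
                   pam_respects_dendro = FALSE, merge_cut_height = 0.25,
                   kme_threshold = 0.8),
    selection = list(effect_threshold = 1.0, pca_threshold = 0.25),
    ora = list(p_cut = 0.01, q_cut = 0.01),
    ppi = list(hub_min_degree = 30),
    integration = list(high_expression_floor = 10)
  )
}

#' Build and validate a pipeline configuration
#'
#' A single nested configuration drives the whole pipeline; every analysis
#' constant (missingness cutoff 0.5, soft-threshold power, minimum module
#' size 30, deep split 3, merge height 0.25, kME 0.8, enrichment cutoffs
#' 0.01, hub degree 30, high-expression floor 10) has a configuration home
#' with its standard value as default. Unknown keys are rejected before any
#' computation. Inputs can be given as file paths (`paths$...`) or as
#' in-memory objects (`data$...`).
#'
#' @param ... Named blocks overriding the defaults (see
#'   `coexprot:::config_schema()` for the full layout), or a single list.
#' @return Validated config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  schema <- config_schema()
  bad <- setdiff(names(user), names(schema))
  if (length(bad)) abort(sprintf("unknown config key(s): %s",
                                 paste(bad, collapse = ", ")))
  cfg <- schema
  for (k in names(user)) {
    if (is.list(schema[[k]]) && length(schema[[k]]) && !is.null(names(schema[[k]]))) {
      if (!is.list(user[[k]])) abort(sprintf("config block `%s` must be a list", k))
      badk <- setdiff(names(user[[k]]), names(schema[[k]]))
      if (length(badk)) abort(sprintf("unknown config key(s) in `%s`: %s",
                                      k, paste(badk, collapse = ", ")))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return Validated config (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
  })
}

resolve_input <- function(cfg, what, reader) {
  if (!is.null(cfg$data[[what]])) return(cfg$data[[what]])
  if (!is.null(cfg$paths[[what]])) return(reader(cfg$paths[[what]]))
  NULL
}

#' Run the full analysis for one dataset
#'
#' Executes the staged workflow — optional Hi3 quantification from a peptide
#' table, preprocessing (ambiguous-ID removal, missingness filter,
#' dataset-appropriate median normalization, 6-decimal standardization),
#' co-expression module detection, and module selection/annotation — and
#' persists every stage's outputs under `<outdir>/<dataset>`: normalized
#' matrix, partition, eigengenes, kME table, contrast report, disease-count
#' table, enrichment results, dendrogram (Newick), soft-threshold report,
#' machine-readable `report.json`, and a log of protein counts after each
#' filter.
#'
#' @param config A [pipeline_config()].
#' @param dataset `"invitro"` or `"biopsy"`; decides the normalization
#'   scheme, the treated/control contrast, and the default power (2 in
#'   vitro, 5 biopsy).
#' @return Invisibly, a list of class `"dataset_run"` with all stage
#'   results and the output directory.
#' @export
run_dataset <- function(config, dataset = c("invitro", "biopsy")) {
  dataset <- match.arg(dataset)
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  design <- stage("inputs", {
    d <- resolve_input(config, "design", read_design_tsv)
    if (is.null(d)) abort("no design provided")
    d
  })
  peptides <- resolve_input(config, "peptides", read_protein_tsv)
  mat <- resolve_input(config, "protein_matrix", read_protein_tsv)

  if (!is.null(peptides)) {
    mat <- stage("quantify", {
      cons <- consolidate_peptides(peptides)
      say("peptides: %d rows consolidated to %d", nrow(peptides), nrow(cons))
      inf <- infer_proteins(cons)
      say("proteins after inference: %d", length(unique(inf$protein)))
      hi3_quantify(inf, n_top = config$quantify$n_top,
                   aggregate = config$quantify$aggregate)
    })
  }
  if (is.null(mat)) abort("no protein matrix or peptide table provided")
  say("proteins quantified: %d", nrow(mat))

  norm <- stage("preprocess", {
    id_map <- resolve_input(config, "id_map", read_protein_tsv)
    if (!is.null(id_map)) {
      mat <- drop_ambiguous_ids(mat, id_map)
      say("proteins with a unique UniProt ID: %d", nrow(mat))
    }
    mat <- filter_missing(mat, config$preprocess$max_missing_fraction)
    say("proteins after missingness filter: %d", nrow(mat))
    nr <- if (dataset == "invitro") normalize_invitro(mat, design)
          else normalize_biopsy(mat)
    nr$matrix <- standardize_decimals(nr$matrix, config$preprocess$digits)
    nr
  })
  mat <- norm$matrix

  fit <- stage("coexnet", {
    net <- config$network
    net$power <- net$power %||% (if (dataset == "invitro") 2 else 5)
    params <- network_params(
      power = net$power, min_cluster_size = net$min_cluster_size,
      deep_split = net$deep_split,
      pam_respects_dendro = net$pam_respects_dendro,
      merge_cut_height = net$merge_cut_height,
      kme_threshold = net$kme_threshold)
    fit_coexpression_modules(mat, params)
  })
  sizes <- module_sizes(fit$partition)
  say("modules: %d (%s)", sum(sizes$module != "grey"),
      paste(sprintf("%s=%d", sizes$module, sizes$n_proteins), collapse = ", "))
  say("weighted proteins: %d", length(fit$weighted))

  sel <- stage("module_select", {
    contrasts <- if (is.null(fit$eigengenes)) NULL else
      eigengene_contrast(fit$eigengenes, design, mat, fit$partition)
    selected <- if (is.null(contrasts)) character() else
      select_affected(contrasts, config$selection$effect_threshold,
                      config$selection$pca_threshold)
    disease <- resolve_input(config, "disease_set",
                             function(p) read_gmt(p)[[1]])
    counts <- if (!is.null(disease))
      annotate_disease(fit$partition, fit$weighted, disease) else NULL
    pathways <- resolve_input(config, "pathways", read_gmt)
    enrich <- if (!is.null(pathways) && length(selected)) {
      query <- fit$partition$accession[fit$partition$module %in% selected]
      ora(query, fit$partition$accession, pathways,
          p_cut = config$ora$p_cut, q_cut = config$ora$q_cut)
    } else NULL
    list(contrasts = contrasts, selected = selected, counts = counts,
         enrichment = enrich)
  })
  say("selected modules: %s",
      if (length(sel$selected)) paste(sel$selected, collapse = ", ") else "none")

  run <- structure(list(
    dataset = dataset, design = design, matrix = mat,
    normalization = norm$report, fit = fit,
    contrasts = sel$contrasts, selected = sel$selected,
    counts = sel$counts, enrichment = sel$enrichment,
    log = log_lines, outdir = NULL
  ), class = "dataset_run")

  if (!is.null(config$outdir)) {
    run$outdir <- file.path(config$outdir, dataset)
    write_dataset_run(run, run$outdir, config)
  }
  invisible(run)
}

write_dataset_run <- function(run, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_design_tsv(run$design, file.path(dir, "design.tsv"))
  write_protein_tsv(run$matrix, file.path(dir, "matrix_normalized.tsv"))
  readr::write_tsv(run$normalization, file.path(dir, "normalization.tsv"))
  readr::write_tsv(run$fit$partition, file.path(dir, "partition.tsv"))
  readr::write_tsv(run$fit$soft_threshold, file.path(dir, "soft_threshold.tsv"))
  if (!is.null(run$fit$eigengenes)) {
    readr::write_tsv(run$fit$eigengenes, file.path(dir, "eigengenes.tsv"))
  }
  if (!is.null(run$fit$kme)) {
    readr::write_tsv(run$fit$kme, file.path(dir, "kme.tsv"))
  }
  readr::write_lines(run$fit$weighted, file.path(dir, "weighted.txt"))
  if (!is.null(run$contrasts)) {
    readr::write_tsv(run$contrasts, file.path(dir, "contrasts.tsv"))
  }
  if (!is.null(run$counts)) {
    readr::write_tsv(run$counts, file.path(dir, "counts.tsv"))
  }
  if (!is.null(run$enrichment)) {
    readr::write_tsv(run$enrichment, file.path(dir, "enrichment.tsv"))
  }
  write_newick(run$fit$dendrogram, file.path(dir, "dendrogram.nwk"))
  yaml::write_yaml(unclass(config)[setdiff(names(config), "data")],
                   file.path(dir, "params.yaml"))
  report <- c(
    list(dataset = run$dataset,
         selected_modules = as.list(run$selected),
         n_weighted = length(run$fit$weighted)),
    as.list(glance(run$fit))
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_lines(run$log, file.path(dir, "log.txt"))
  invisible(dir)
}

read_dataset_run <- function(dir) {
  list(
    design = read_design_tsv(file.path(dir, "design.tsv")),
    matrix = read_protein_tsv(file.path(dir, "matrix_normalized.tsv")),
    partition = readr::read_tsv(file.path(dir, "partition.tsv"),
                                show_col_types = FALSE, progress = FALSE),
    weighted = readr::read_lines(file.path(dir, "weighted.txt"))
  )
}

#' Integrate two analyzed datasets
#'
#' Combines two completed [run_dataset()] results (in-memory objects or
#' result directories): cross-dataset protein overlap and weighted-protein
#' sets, per-dataset log2 fold-change tables, an induced PPI network on the
#' weighted-in-either proteins with orphan removal, hub calling and disease
#' flagging, and a high-expression filter over the integration candidates
#' (weighted-in-both proteins plus hubs). Writes a machine-readable
#' `report.json` plus TSV tables when `config$outdir` is set.
#'
#' @param config A [pipeline_config()]; `data`/`paths` may provide
#'   `ppi_edges` and `disease_set`.
#' @param run_a,run_b `dataset_run` objects or result directory paths.
#' @return Invisibly, a list of class `"integration_run"`.
#' @export
run_integration <- function(config, run_a, run_b) {
  stopifnot(inherits(config, "pipeline_config"))
  load_run <- function(r) {
    if (inherits(r, "dataset_run")) {
      list(design = r$design, matrix = r$matrix,
           partition = r$fit$partition, weighted = r$fit$weighted,
           dataset = r$dataset)
    } else {
      if (!file.exists(file.path(r, "partition.tsv"))) {
        abort(sprintf("missing upstream artifact: %s",
                      file.path(r, "partition.tsv")))
      }
      c(read_dataset_run(r), list(dataset = basename(r)))
    }
  }
  a <- stage("integration inputs", load_run(run_a))
  b <- stage("integration inputs", load_run(run_b))

  ov <- overlap_datasets(a$partition$accession, b$partition$accession,
                         a$weighted, b$weighted)

  fc <- stage("log2fc", {
    fc_for <- function(r) {
      if (all(r$design$dataset_kind == "biopsy")) log2fc_biopsy(r$matrix, r$design)
      else log2fc_invitro(r$matrix, r$design)
    }
    list(a = fc_for(a), b = fc_for(b))
  })

  disease <- resolve_input(config, "disease_set", function(p) read_gmt(p)[[1]])
  edges <- resolve_input(config, "ppi_edges", read_edge_tsv)
  ppi <- NULL; hubs <- NULL; n_orphans <- NA_integer_
  if (!is.null(edges) && length(ov$weighted_either)) {
    ppi <- stage("ppi", {
      g <- build_induced_network(edges, ov$weighted_either)
      if (!is.null(disease)) {
        g <- flag_disease_nodes(g, disease, query = ov$weighted_either)
      }
      pruned <- remove_orphans(g)
      n_orphans <<- pruned$n_removed
      if (!is.null(disease)) {
        pruned$graph <- flag_disease_nodes(pruned$graph, disease,
                                           query = ov$weighted_either)
      }
      list(full = g, pruned = pruned$graph)
    })
    hubs <- find_hubs(ppi$pruned, config$ppi$hub_min_degree)
  }

  high_expr <- stage("high_expression", {
    candidates <- union(ov$weighted_both,
                        if (!is.null(hubs)) hubs$accession else character())
    floor <- config$integration$high_expression_floor
    if (length(candidates)) {
      ha <- high_expression_filter(
        dplyr::filter(a$matrix, .data$accession %in% candidates), floor)
      hb <- high_expression_filter(
        dplyr::filter(b$matrix, .data$accession %in% candidates), floor)
      intersect(ha, hb)
    } else character()
  })

  res <- structure(list(
    overlap = ov, log2fc_a = fc$a, log2fc_b = fc$b,
    ppi = ppi, hubs = hubs, n_orphans_removed = n_orphans,
    high_expression = high_expr
  ), class = "integration_run")

  if (!is.null(config$outdir)) {
    dir <- file.path(config$outdir, "integration")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(fc$a, file.path(dir, sprintf("log2fc_%s.tsv", a$dataset)))
    readr::write_tsv(fc$b, file.path(dir, sprintf("log2fc_%s.tsv", b$dataset)))
    if (!is.null(ppi)) {
      readr::write_tsv(tidy(ppi$pruned, config$ppi$hub_min_degree),
                       file.path(dir, "ppi_nodes.tsv"))
      write_sif(ppi_edges(ppi$pruned), file.path(dir, "ppi_edges.sif"))
    }
    report <- list(
      n_common = length(ov$common),
      n_weighted_either = length(ov$weighted_either),
      n_weighted_both = length(ov$weighted_both),
      pct_weighted_either = ov$pct_weighted_either,
      weighted_both = as.list(ov$weighted_both),
      n_orphans_removed = n_orphans,
      hubs = if (!is.null(hubs)) as.list(hubs$accession) else list(),
      pct_disease_query = if (!is.null(ppi))
        attr(ppi$pruned, "pct_disease_query") else NULL,
      high_expression = as.list(high_expr)
    )
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    res$outdir <- dir
  }
  invisible(res)
}
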