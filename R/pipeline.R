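#' Default pipeline configuration
#'
#' One nested list holding every stage parameter at its default, plus either
#' a `simulate` block ([synth_config()] arguments) or an `inputs` block of
#' file paths (`otu`, `taxonomy`, `meta`, `functions`, `otu_kind`). The
#' single global `seed` is fanned out deterministically to each stage.
#'
#' @param seed Global seed.
#' @param simulate List of [synth_config()] overrides, or NULL when reading
#'   inputs from disk.
#' @param inputs List of input paths, or NULL when simulating.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1, simulate = list(), inputs = NULL) {
  list(
    seed = seed,
    simulate = simulate,
    inputs = inputs,
    core = list(top_frac = 0.10, occ_frac = 0.95),
    emf = list(alpha = 0.05),
    ordination = list(n_permutations = 9999),
    network = list(min_cluster_size = NULL, kme_threshold = 0.9,
                   target_r2 = 0.9, beta = NULL),
    drivers = list(n_trees = 1000, rf_permutations = 0,
                   trophic_basis = "count")
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [default_config()].
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]]))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    else cfg[[k]] <- user[[k]]
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: data (simulate or load), core-taxa
#' identification, EMF and its zone comparisons, Bray-Curtis PCoA + ANOSIM
#' on the core community, co-occurrence network on the core taxa, and driver
#' analyses (random-forest importance, cluster-EMF regressions, trophic
#' ratios, zone-wise cluster comparisons). A stage failure is recorded in
#' the report and downstream stages are skipped. With `outdir` set, stage
#' tables are written as TSV and the report as JSON.
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()].
#' @param outdir Output directory, or NULL to skip writing.
#' @return List of class `run_report` with one block per stage plus
#'   `headline` statistics.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  report <- list(seed = config$seed, stages = list(), headline = list())
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env()

  run_stage <- function(name, fun) {
    if (!is.null(report$error)) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch({
      warns <- character(0)
      out <- withCallingHandlers(fun(), warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
      list(status = "ok", warnings = warns, value = out)
    }, error = function(e) list(status = "error", message = conditionMessage(e)))
    if (res$status == "error") {
      report$error <<- list(stage = name, message = res$message)
      report$stages[[name]] <<- res
    } else {
      report$stages[[name]] <<- res[c("status", "warnings")]
      assign(name, res$value, envir = env)
    }
    invisible(NULL)
  }

  run_stage("data", function() {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      otu <- read_otu_table(inp$otu, kind = inp$otu_kind %||% "counts")
      list(otu = otu, taxonomy = read_taxonomy(inp$taxonomy),
           meta = read_metadata(inp$meta),
           fx = read_function_table(inp$functions), truth = NULL)
    } else {
      sc <- do.call(synth_config, c(config$simulate,
                                    if (is.null(config$simulate$seed))
                                      list(seed = config$seed)))
      synth_community(sc)
    }
  })

  run_stage("core", function() {
    dat <- get("data", env)
    al <- align_tables(dat$otu, dat$meta, dat$fx)
    assign("aligned", al, envir = env)
    identify_core(al$otu, top_frac = config$core$top_frac,
                  occ_frac = config$core$occ_frac)
  })

  run_stage("emf", function() {
    al <- get("aligned", env)
    tr <- transform_for_normality(al$fx, alpha = config$emf$alpha)
    emf <- emf_index(tr$fx)
    list(transform_log = tr$log, emf = emf,
         groups = compare_emf_groups(emf, al$meta))
  })

  run_stage("ordination", function() {
    al <- get("aligned", env)
    core <- core_set(get("core", env))
    rel <- to_relative(al$otu)
    sub <- otu_table(
      sweep(rel$values[core, , drop = FALSE], 2,
            colSums(rel$values[core, , drop = FALSE]), "/"),
      kind = "relative")
    d <- bray_curtis(sub)
    zones <- al$meta$zone[match(rownames(d), al$meta$sample_id)]
    pairs <- utils::combn(sort(unique(zones)), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      sel <- zones %in% pairs[, k]
      an <- anosim(d[sel, sel], zones[sel],
                   n_permutations = config$ordination$n_permutations,
                   seed = config$seed)
      data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
                 R = an$R, p.value = an$p.value)
    }))
    list(distance = d, pcoa = pcoa(d),
         anosim = anosim(d, zones,
                         n_permutations = config$ordination$n_permutations,
                         seed = config$seed),
         anosim_pairwise = pairwise)
  })

  run_stage("network", function() {
    al <- get("aligned", env)
    core <- core_set(get("core", env))
    build_network(al$otu, subset = core,
                  beta = config$network$beta,
                  min_cluster_size = config$network$min_cluster_size,
                  kme_threshold = config$network$kme_threshold,
                  target_r2 = config$network$target_r2)
  })

  run_stage("drivers", function() {
    al <- get("aligned", env)
    dat <- get("data", env)
    core_tab <- get("core", env)
    net <- get("network", env)
    emf <- get("emf", env)$emf
    X <- t(taxon_profiles(al$otu, transform = "log"))
    imp <- rf_importance(X, emf$emf[rownames(X)],
                         is_core = core_tab$is_core[match(colnames(X), core_tab$otu_id)],
                         n_trees = config$drivers$n_trees,
                         n_permutations = config$drivers$rf_permutations,
                         seed = config$seed)
    list(importance = imp,
         core_contrast = compare_core_importance(imp),
         regression = ols_cluster_emf(net$cluster_abundance, emf),
         trophic = trophic_ratio(net$labels, dat$taxonomy,
                                 basis = config$drivers$trophic_basis,
                                 x = al$otu),
         zone_comparison = compare_cluster_abundance_by_zone(
           net$cluster_abundance, al$meta))
  })

  if (is.null(report$error)) {
    core_tab <- get("core", env)
    net <- get("network", env)
    emfb <- get("emf", env)
    ordn <- get("ordination", env)
    drv <- get("drivers", env)
    report$headline <- list(
      n_taxa = nrow(get("aligned", env)$otu$values),
      n_core = sum(core_tab$is_core),
      emf_kruskal_p = emfb$groups$kruskal$p.value,
      emf_pairwise = emfb$groups$pairwise,
      anosim_R = ordn$anosim$R,
      anosim_p = ordn$anosim$p.value,
      anosim_pairwise = ordn$anosim_pairwise,
      pcoa_explained = ordn$pcoa$explained[1:min(2, length(ordn$pcoa$explained))],
      beta = net$beta,
      n_clusters = max(net$labels),
      n_hubs = sum(lengths(net$hubs)),
      core_importance_p = drv$core_contrast$p.value,
      regression = drv$regression
    )
  }

  if (!is.null(outdir)) write_pipeline_outputs(env, report, outdir)
  structure(report, class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(env, report, outdir) {
  p <- function(...) file.path(outdir, ...)
  if (exists("data", env)) {
    dat <- get("data", env)
    write_otu_table(dat$otu, p("otu_counts.tsv"))
    write_taxonomy(dat$taxonomy, p("taxonomy.tsv"))
    write_metadata(dat$meta, p("metadata.tsv"))
    write_function_table(dat$fx, p("functions.tsv"))
  }
  if (exists("core", env))
    utils::write.table(get("core", env), p("core_assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (exists("emf", env)) {
    emf <- get("emf", env)
    utils::write.table(
      data.frame(sample_id = names(emf$emf$emf), emf = emf$emf$emf),
      p("emf.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (exists("network", env)) {
    net <- get("network", env)
    utils::write.table(
      data.frame(otu_id = names(net$labels), cluster = net$labels),
      p("cluster_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_tsv_matrix(net$cluster_abundance, p("cluster_abundance.tsv"),
                     id_col = "cluster")
    write_tsv_matrix(net$kme, p("kme.tsv"), id_col = "otu_id")
    edges <- which(upper.tri(net$adjacency), arr.ind = TRUE)
    el <- data.frame(node1 = rownames(net$adjacency)[edges[, 1]],
                     node2 = rownames(net$adjacency)[edges[, 2]],
                     weight = net$adjacency[edges])
    utils::write.table(el, p("edges.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (exists("drivers", env)) {
    drv <- get("drivers", env)
    utils::write.table(drv$importance, p("importance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(drv$regression, p("cluster_emf_regression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(drv$trophic, p("trophic_ratio.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(serialize_report(report), p("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

serialize_report <- function(report) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(report))
}
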