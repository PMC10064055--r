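#' Configure an end-to-end analysis run
#'
#' Bundles all inputs and tuning parameters of [run_pipeline()]. Provide
#' either file paths (`epi_path`, `endo_path`, `tree_path`) or a
#' `synthetic` block (a list of arguments for
#' [simulate_paired_communities()]; the tree is then simulated too).
#'
#' @param epi_path,endo_path Paths to tab-separated OTU tables, or `NULL`.
#' @param tree_path Path to the host tree in newick, or `NULL`.
#' @param synthetic Optional list of overrides for
#'   [simulate_paired_communities()] (e.g. `n_hosts`, `n_otus`,
#'   `signal_lambda`); used when no paths are given.
#' @param min_reads Low-count filter threshold (default 10).
#' @param rarefaction_depth `"min"` (rarefy to the minimum sample total),
#'   an integer depth, or `NA` to skip rarefaction.
#' @param n_null Null matrices per network metric standardisation.
#' @param n_perm_anosim,n_perm_mantel,n_perm_k Permutation counts.
#' @param n_rep_extinction Replicates for the extinction simulation.
#' @param seed Master seed; every stage derives its own named substream.
#' @param stages Character vector of stages to run, a subset of
#'   `c("preprocess", "community", "signal", "network", "robustness")`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(epi_path = NULL, endo_path = NULL, tree_path = NULL,
                            synthetic = NULL, min_reads = 10,
                            rarefaction_depth = "min", n_null = 1000,
                            n_perm_anosim = 9999, n_perm_mantel = 999,
                            n_perm_k = 999, n_rep_extinction = 100,
                            seed = 1L,
                            stages = c("preprocess", "community", "signal",
                                       "network", "robustness")) {
  have_paths <- !is.null(epi_path) && !is.null(endo_path) && !is.null(tree_path)
  if (!have_paths && is.null(synthetic)) {
    abort("config needs either all three input paths or a `synthetic` block")
  }
  if (have_paths) {
    for (p in c(epi_path, endo_path, tree_path)) {
      if (!file.exists(p)) abort(sprintf("input path does not exist: %s", p))
    }
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(
      epi_path = epi_path, endo_path = endo_path, tree_path = tree_path,
      synthetic = synthetic, min_reads = min_reads,
      rarefaction_depth = rarefaction_depth, n_null = n_null,
      n_perm_anosim = n_perm_anosim, n_perm_mantel = n_perm_mantel,
      n_perm_k = n_perm_k, n_rep_extinction = n_rep_extinction,
      seed = as.integer(seed), stages = stages
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the study pathway in order — preprocessing (low-count filter,
#' rarefaction, OTU partition, richness and paired t-test), community
#' statistics (Hellinger + Bray-Curtis, NMDS, ANOSIM between compartments,
#' one-tailed Mantel of community similarity against host phylogenetic
#' distance per compartment), phylogenetic signal of log richness
#' (Blomberg's K, Pagel's lambda), network metrics with swap-web
#' standardisation, and secondary-extinction robustness — and collects
#' every result in an `analysis_report`. Each stage consumes a seed derived
#' from the master seed and the stage name, so results are reproducible and
#' stages can be skipped without perturbing the others.
#'
#' @param config A [pipeline_config()].
#' @return An `analysis_report` (named list of stage results plus
#'   provenance), printable and serialisable with [write_report()].
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config")
  seed <- config$seed
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("phyllonet")),
    seed = seed, stages = config$stages,
    config_hash = config_hash(config)
  ))

  # inputs
  if (!is.null(config$synthetic)) {
    sim <- config$synthetic
    n_hosts <- sim$n_hosts %||% 11L
    tree <- simulate_tree(n_hosts, seed = stage_seed(seed, "tree"))
    args <- sim[setdiff(names(sim), "n_hosts")]
    tables <- do.call(
      simulate_paired_communities,
      c(list(tree = tree, seed = stage_seed(seed, "communities")), args)
    )
    epi <- tables$epi
    endo <- tables$endo
  } else {
    epi <- read_otu_table(config$epi_path)
    endo <- read_otu_table(config$endo_path)
    tree <- read_newick(config$tree_path)
  }

  if ("preprocess" %in% config$stages) {
    epi <- filter_low_count(epi, config$min_reads)
    endo <- filter_low_count(endo, config$min_reads)
    depth <- config$rarefaction_depth
    if (identical(depth, "min")) {
      depth <- min(rowSums(otu_counts(epi)), rowSums(otu_counts(endo)))
    }
    if (!is.na(depth) && !is.null(depth)) {
      epi <- rarefy(epi, depth, seed = stage_seed(seed, "rarefy_epi"))
      endo <- rarefy(endo, depth, seed = stage_seed(seed, "rarefy_endo"))
    }
    rich_epi <- richness(epi)
    rich_endo <- richness(endo)
    report$partition <- partition_otus(epi, endo)
    report$richness <- dplyr::full_join(
      dplyr::rename(rich_epi, epiphyte = "richness"),
      dplyr::rename(rich_endo, endophyte = "richness"),
      by = "sample_id"
    )
    report$richness_test <- tidy(paired_t_log(
      setNames(rich_epi$richness, rich_epi$sample_id),
      setNames(rich_endo$richness, rich_endo$sample_id),
      tail = "greater"
    ))
  }

  if ("community" %in% config$stages) {
    he <- hellinger(epi)
    hn <- hellinger(endo)
    rownames(he) <- paste0("epi_", rownames(he))
    rownames(hn) <- paste0("endo_", rownames(hn))
    all_otus <- union(colnames(he), colnames(hn))
    pad <- function(m) {
      out <- matrix(0, nrow(m), length(all_otus),
                    dimnames = list(rownames(m), all_otus))
      out[, colnames(m)] <- m
      out
    }
    comb <- rbind(pad(he), pad(hn))
    d_all <- bray_curtis(comb)
    grp <- setNames(
      rep(c("epiphyte", "endophyte"), c(nrow(he), nrow(hn))),
      rownames(comb)
    )
    report$nmds <- glance(nmds(d_all, k = 2, seed = stage_seed(seed, "nmds")))
    report$anosim <- tidy(anosim(d_all, grp, n_perm = config$n_perm_anosim,
                                 seed = stage_seed(seed, "anosim")))
    phylo_d <- cophenetic_distances(tree)
    mantel_one <- function(tab, label) {
      sim_m <- 1 - bray_curtis(hellinger(tab)) # community similarity
      diag(sim_m) <- 0
      res <- mantel(sim_m, phylo_d, tail = "less",
                    n_perm = config$n_perm_mantel,
                    seed = stage_seed(seed, paste0("mantel_", label)))
      tidy(res)
    }
    report$mantel <- dplyr::bind_rows(
      dplyr::mutate(mantel_one(epi, "epi"), compartment = "epiphyte"),
      dplyr::mutate(mantel_one(endo, "endo"), compartment = "endophyte")
    )
  }

  if ("signal" %in% config$stages) {
    signal_one <- function(tab, label) {
      r <- richness(tab)
      trait <- setNames(log(r$richness + 1), r$sample_id)
      dplyr::bind_rows(
        tidy(blomberg_k(tree, trait, n_perm = config$n_perm_k,
                        seed = stage_seed(seed, paste0("k_", label)))),
        tidy(pagel_lambda(tree, trait))
      )
    }
    report$signal <- dplyr::bind_rows(
      dplyr::mutate(signal_one(epi, "epi"), compartment = "epiphyte"),
      dplyr::mutate(signal_one(endo, "endo"), compartment = "endophyte")
    )
  }

  networks <- NULL
  if (any(c("network", "robustness") %in% config$stages)) {
    networks <- list(
      epiphyte = suppressWarnings(interaction_matrix(otu_counts(epi))),
      endophyte = suppressWarnings(interaction_matrix(otu_counts(endo)))
    )
  }

  if ("network" %in% config$stages) {
    report$network <- purrr::map_dfr(names(networks), function(nm) {
      ens <- network_null_report(
        networks[[nm]], n_null = config$n_null,
        seed = stage_seed(seed, paste0("network_", nm))
      )
      dplyr::mutate(purrr::map_dfr(ens, glance), network = nm)
    })
  }

  if ("robustness" %in% config$stages) {
    report$robustness <- purrr::map_dfr(names(networks), function(nm) {
      purrr::map_dfr(c("plants", "fungi"), function(axis) {
        cur <- simulate_extinctions(
          networks[[nm]], primary_axis = axis,
          n_rep = config$n_rep_extinction,
          seed = stage_seed(seed, paste0("ext_", nm, "_", axis))
        )
        dplyr::mutate(glance(fit_extinction_curve(cur)), network = nm)
      })
    })
  }

  structure(report, class = "analysis_report")
}

config_hash <- function(config) {
  flat <- config[setdiff(names(config), c("epi_path", "endo_path", "tree_path"))]
  s <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("%08x", stage_seed(0L, as.character(s)))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (nm in setdiff(names(x), "provenance")) {
    cat("--", nm, "--\n")
    print(x[[nm]])
  }
  cat(sprintf(
    "seed %d, config %s, phyllonet %s\n",
    x$provenance$seed, x$provenance$config_hash, x$provenance$package_version
  ))
  invisible(x)
}

#' Serialise an analysis report
#'
#' Writes the report as machine-readable JSON plus a human-readable
#' markdown summary of the test statistics and network z-scores. Output is
#' deterministic: no timestamps or absolute paths, so the same config and
#' seed produce byte-identical files.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Files: `report.json`, `summary.md`.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "analysis_report")) abort("`report` must be an analysis_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  md <- c("# Analysis report", "")
  fmt_tbl <- function(df) {
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(format(r, digits = 4), collapse = " | "), " |"))
    c(header, sep, rows, "")
  }
  for (nm in setdiff(names(report), "provenance")) {
    md <- c(md, paste("##", nm), "")
    part <- report[[nm]]
    if (is.data.frame(part)) md <- c(md, fmt_tbl(part))
  }
  md <- c(md, sprintf("Seed: %d. Config hash: %s.",
                      report$provenance$seed, report$provenance$config_hash))
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
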