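# Orchestration: config-driven end-to-end run over all groups, TSV/figure
# outputs, a machine-readable summary of the headline statistics, and a thin
# command-line front end.

#' Build a run configuration
#'
#' Exactly one input mode is active: file paths (annotation, expression,
#' samples) or a simulation profile. Thresholds mirror the analysis
#' defaults.
#'
#' @param out_dir output directory
#' @param seed integer seed for every source of randomness in the run
#' @param annotation,expression,samples input file paths (file mode)
#' @param simulate simulate instead of loading files?
#' @param sim_config optional `xdg_sim_config`; default [paper_profile()]
#'   with `seed`
#' @param groups groups to analyse
#' @param min_fpkm,expressed_threshold,alpha,window_bp,smooth_k,k_clusters
#'   analysis thresholds
#' @param exclude_xist exclude XIST from X-linked aggregates?
#' @param lineage also generate/analyse a paired IT/TE dataset (simulate
#'   mode)?
#' @param n_embryos embryos for the lineage dataset
#' @param figures render PNG figures?
#' @return list of class `xdg_run_config`
#' @export
run_config <- function(out_dir, seed = 1,
                       annotation = NULL, expression = NULL, samples = NULL,
                       simulate = is.null(expression),
                       sim_config = NULL,
                       groups = c("IVF", "SCNT", "SHAM", "DONOR"),
                       min_fpkm = 1, expressed_threshold = 0.1, alpha = 0.05,
                       window_bp = 1e6, smooth_k = 30, k_clusters = 9,
                       exclude_xist = FALSE, lineage = simulate,
                       n_embryos = 19, figures = TRUE) {
  if (!simulate && (is.null(annotation) || is.null(expression) || is.null(samples))) {
    stop("file mode needs annotation, expression and samples paths")
  }
  stopifnot(min_fpkm > 0 || min_fpkm == 0, expressed_threshold > 0,
            alpha > 0, window_bp > 0, smooth_k >= 1, k_clusters >= 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "xdg_run_config")
}

#' Write a simulation configuration as YAML
#' @param config `xdg_sim_config`
#' @param path output path
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "xdg_sim_config"))
  x <- unclass(config)
  # named atomic vectors serialise as YAML maps only when given as lists
  for (nm in c("x_upregulation", "xist_fpkm")) x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration from YAML (seed is mandatory)
#' @param path YAML file written by [write_sim_config()] or by hand
#' @return `xdg_sim_config`
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$seed)) stop("serialized configuration lacks a seed")
  for (nm in c("x_upregulation", "xist_fpkm")) {
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  }
  do.call(simulation_config, x)
}

#' Build a run configuration from a YAML file
#' @param path YAML whose keys are [run_config()] arguments
#' @return `xdg_run_config`
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

pipeline_log <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full dosage pipeline
#'
#' Stages: input (load or simulate), QC, per-group dosage statistics,
#' chromosome window profiles, sex-differential expression, trajectory
#' clustering (when donor cells are present), lineage comparison (when IT/TE
#' samples are present), and a consolidated machine-readable summary
#' (`summary.json`). Deterministic given the seed; every output file carries
#' the configuration hash in its comment header.
#'
#' @param config `xdg_run_config` from [run_config()]
#' @return the output directory, invisibly; the headline summary is also
#'   returned as attribute `summary`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "xdg_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # the hash covers analysis-relevant parameters, not where outputs land
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  hdr <- list(config_hash = hash, seed = config$seed)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  pipeline_log(logf, "xdosage ", xdg_version(), " run, config hash ", hash)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ds <- stage("input", {
    if (config$simulate) {
      sc <- config$sim_config %||% paper_profile(seed = config$seed)
      d <- generate_dataset(sc, groups = config$groups)
      write_dataset(d, file.path(config$out_dir, "inputs"), hdr)
      d
    } else {
      validate_dataset(load_annotation(config$annotation),
                       load_expression(config$expression),
                       load_samples(config$samples))
    }
  })
  pipeline_log(logf, "dataset: ", nrow(ds$matrix), " genes x ",
               ncol(ds$matrix), " samples")
  groups <- intersect(config$groups, unique(ds$samples$group))
  summary <- list(config_hash = hash, seed = config$seed)

  stage("qc", {
    write_xdg_tsv(as.data.frame(sample_correlation(ds)),
                  file.path(config$out_dir, "qc_correlation.tsv"), hdr)
    sx <- verify_sex_markers(ds)
    write_xdg_tsv(sx, file.path(config$out_dir, "qc_sex_markers.tsv"), hdr)
    summary$sex_marker_concordance <- mean(sx$concordant)
  })

  gm <- group_means(ds)
  sexed <- intersect(groups,
                     unique(ds$samples$group[ds$samples$sex == "female"])) |>
    intersect(unique(ds$samples$group[ds$samples$sex == "male"]))

  stage("dosage", {
    xa <- xa_ratios(ds, expressed_min_fpkm = config$expressed_threshold,
                    exclude_xist = config$exclude_xist)
    write_xdg_tsv(xa, file.path(config$out_dir, "xa_summary.tsv"), hdr)
    for (g in sexed) {
      fmx <- fm_ratios(gm, g, min_fpkm = config$min_fpkm,
                       gene_class = "x_linked",
                       exclude_xist = config$exclude_xist)
      write_xdg_tsv(fmx, file.path(config$out_dir,
                                   sprintf("fm_ratios_%s.tsv", g)), hdr)
      write_xdg_tsv(fm_histogram(fmx),
                    file.path(config$out_dir,
                              sprintf("fm_histogram_%s.tsv", g)), hdr)
      pr <- fm_exceed_proportions(fmx)
      summary[[paste0("fm_mean_ratio_", g)]] <-
        fm_mean_ratio(gm, g, min_fpkm = config$min_fpkm,
                      exclude_xist = config$exclude_xist)
      summary[[paste0("fm_gt1_pct_", g)]] <- 100 * unname(pr["gt1"])
      summary[[paste0("fm_gt2_pct_", g)]] <- 100 * unname(pr["gt2"])
      summary[[paste0("xa_test_p_", g)]] <- sexed_xa_test(xa, g)
    }
    for (g in groups) for (sx in unique(ds$samples$sex[ds$samples$group == g])) {
      summary[[sprintf("xa_mean_%s_%s", sx, g)]] <-
        mean(xa$xa_ratio[xa$group == g & xa$sex == sx], na.rm = TRUE)
    }
    summary$expressed_x_counts <-
      as.list(expressed_counts(gm, "x_linked", config$expressed_threshold))
  })

  stage("windows", {
    ref_ok <- "IVF" %in% groups && any(ds$samples$sex == "male" &
                                         ds$samples$group == "IVF")
    if (ref_ok) {
      ref <- window_sums(ds, c(sex = "male", group = "IVF"),
                         window_bp = config$window_bp)
      profs <- list()
      for (g in groups) for (sx in unique(ds$samples$sex[ds$samples$group == g])) {
        p <- window_sums(ds, c(sex = sx, group = g),
                         window_bp = config$window_bp)
        p <- smooth_profile(relative_profile(p, ref), k = config$smooth_k)
        p$cell <- cell_label(sx, g)
        profs[[cell_label(sx, g)]] <- p
      }
      allp <- do.call(rbind, profs)
      write_xdg_tsv(allp, file.path(config$out_dir, "window_profiles.tsv"), hdr)
      if (config$figures) {
        grDevices::png(file.path(config$out_dir, "window_profile_X.png"),
                       width = 900, height = 500)
        plot_window_profiles(profs, chrom = "X")
        grDevices::dev.off()
      }
    }
  })

  stage("differential", {
    deg_sets <- list()
    for (g in sexed) {
      if (sum(ds$samples$group == g & ds$samples$sex == "female") < 2) next
      degs <- sex_de_test(ds, g, alpha = config$alpha,
                          min_mean_fpkm = config$expressed_threshold)
      write_xdg_tsv(degs, file.path(config$out_dir,
                                    sprintf("degs_%s.tsv", g)), hdr)
      cls <- classify_degs(degs)
      deg_sets[[g]] <- cls$xdegs
      summary[[paste0("n_xdeg_", g)]] <- nrow(cls$xdegs)
      summary[[paste0("n_adeg_", g)]] <- nrow(cls$adegs)
      summary[[paste0("xdeg_female_high_pct_", g)]] <-
        100 * unname(cls$proportions["xdeg_female_high"])
      write_xdg_tsv(volcano_table(degs),
                    file.path(config$out_dir,
                              sprintf("volcano_%s.tsv", g)), hdr)
    }
    if (all(c("IVF", "SCNT") %in% names(deg_sets))) {
      ov <- overlap_sets(deg_sets$IVF, deg_sets$SCNT)
      write_xdg_tsv(data.frame(set = names(ov$counts), count = ov$counts),
                    file.path(config$out_dir, "xdeg_overlap_IVF_SCNT.tsv"), hdr)
      summary$xdeg_overlap_IVF_SCNT <- unname(ov$counts["both"])
    }
  })

  stage("clustering", {
    if (all(c("DONOR", "SCNT", "IVF") %in% groups)) {
      for (sx in SEXES) {
        traj <- trajectory_matrix(ds, sex = sx)
        cl <- kmeans_trajectories(traj, k = config$k_clusters,
                                  seed = config$seed)
        write_xdg_tsv(data.frame(gene_id = names(cl$assignment),
                                 cluster = unname(cl$assignment)),
                      file.path(config$out_dir,
                                sprintf("clusters_%s.tsv", sx)), hdr)
      }
    }
    hm <- heatmap_matrix(ds)
    write_xdg_tsv(data.frame(gene_id = rownames(hm$matrix), hm$matrix,
                             check.names = FALSE),
                  file.path(config$out_dir, "heatmap_matrix.tsv"), hdr)
    if (config$figures) {
      grDevices::png(file.path(config$out_dir, "heatmap_X.png"),
                     width = 800, height = 1000)
      plot_heatmap(hm)
      grDevices::dev.off()
    }
  })

  lin_p <- NULL
  stage("lineage", {
    has_split <- any(ds$samples$lineage %in% c("IT", "TE"))
    lds <- if (has_split) ds
    else if (config$simulate && isTRUE(config$lineage)) {
      sc <- config$sim_config %||% paper_profile(seed = config$seed)
      generate_lineage_dataset(sc, n_embryos = config$n_embryos)
    } else NULL
    if (!is.null(lds)) {
      pairs <- lineage_pairs(lds, expressed_min_fpkm = config$expressed_threshold)
      write_xdg_tsv(pairs, file.path(config$out_dir, "lineage.tsv"), hdr)
      summary$lineage_mean_it_te_ratio <- mean(pairs$it_te_ratio, na.rm = TRUE)
      summary$lineage_it_xa_mean <- mean(pairs$it_xa, na.rm = TRUE)
      summary$lineage_te_xa_mean <- mean(pairs$te_xa, na.rm = TRUE)
      summary$lineage_xa_p <- lineage_xa_test(pairs)
      xc <- xist_compare(pairs)
      if (!is.null(xc)) summary$lineage_xist_p <- xc$p_value
    }
  })

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(logf, "done; summary.json written")
  invisible(structure(config$out_dir, summary = summary))
}

#' Consolidated markdown report over a completed run directory
#'
#' Refuses to mix outputs stamped with different configuration hashes.
#'
#' @param out_dir a directory produced by [run_pipeline()]
#' @param path report path (default `report.md` inside `out_dir`)
#' @return report path, invisibly
#' @export
write_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  sj <- file.path(out_dir, "summary.json")
  if (!file.exists(sj)) stop("no summary.json in ", out_dir)
  summary <- jsonlite::read_json(sj)
  tsvs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE,
                     recursive = TRUE)
  hashes <- unique(unlist(lapply(tsvs, function(f) {
    h <- read_xdg_header(f)
    m <- regmatches(h, regexpr("config_hash=[0-9a-f]+", h))
    if (length(m)) sub("config_hash=", "", m) else NULL
  })))
  if (length(hashes) > 1) {
    stop("output directory mixes files from different runs (hashes: ",
         paste(hashes, collapse = ", "), ")")
  }
  lines <- c("# X-dosage analysis report", "",
             sprintf("- config hash: %s", summary$config_hash),
             sprintf("- seed: %s", summary$seed), "",
             "## Headline statistics", "")
  for (nm in setdiff(names(summary), c("config_hash", "seed"))) {
    v <- summary[[nm]]
    lines <- c(lines, sprintf("- %s: %s", nm,
                              paste(format(unlist(v), digits = 4),
                                    collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- figures ---------------------------------------------------------------

#' Plot smoothed relative window profiles for one chromosome
#' @param profiles list of smoothed `xdg_profile` objects (with `cell`)
#' @param chrom chromosome to plot
#' @export
plot_window_profiles <- function(profiles, chrom = "X") {
  cols <- grDevices::hcl.colors(max(length(profiles), 2), "Dark 2")
  first <- TRUE
  i <- 1
  for (p in profiles) {
    pp <- p[p$chrom == chrom & !is.na(p$smoothed), ]
    if (first) {
      graphics::plot(pp$window_start_bp / 1e6, pp$smoothed, type = "l",
                     col = cols[i], xlab = sprintf("chromosome %s (Mb)", chrom),
                     ylab = "smoothed relative expression",
                     ylim = c(0, max(3, max(pp$smoothed))))
      first <- FALSE
    } else {
      graphics::lines(pp$window_start_bp / 1e6, pp$smoothed, col = cols[i])
    }
    i <- i + 1
  }
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", legend = names(profiles),
                   col = cols[seq_along(profiles)], lty = 1, cex = 0.7)
}

#' Render the relative-expression heatmap
#' @param hm result of [heatmap_matrix()]
#' @export
plot_heatmap <- function(hm) {
  m <- hm$matrix
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       show_rownames = FALSE)
  } else {
    graphics::image(t(m[nrow(m):1, ]), axes = FALSE,
                    main = "relative X-linked expression")
  }
}

# ---- CLI -------------------------------------------------------------------

cli_flag <- function(args, name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `simulate` (write the three TSV
#' inputs plus ground truth), `report` (markdown report over a run
#' directory). Shared flags: `--seed`, `--out`; `run` also accepts
#' `--groups` (comma-separated), `--annotation --expression --samples` for
#' file mode, and threshold flags `--min-fpkm --expressed-threshold --alpha`.
#'
#' @param args character vector (default: command line)
#' @return invisibly, the subcommand's result
#' @export
xdosage_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: xdosage <run|simulate|report> [--seed S] [--out DIR] ...\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  seed <- as.integer(cli_flag(args, "seed", "1"))
  out <- cli_flag(args, "out", "xdosage_out")
  groups <- strsplit(cli_flag(args, "groups", "IVF,SCNT,SHAM,DONOR"), ",")[[1]]
  if (cmd == "simulate") {
    ds <- generate_dataset(paper_profile(seed = seed), groups = groups)
    write_dataset(ds, out, list(seed = seed))
    message("wrote simulated inputs to ", out)
    return(invisible(out))
  }
  if (cmd == "run") {
    cfg <- run_config(
      out_dir = out, seed = seed, groups = groups,
      annotation = cli_flag(args, "annotation"),
      expression = cli_flag(args, "expression"),
      samples = cli_flag(args, "samples"),
      min_fpkm = as.numeric(cli_flag(args, "min-fpkm", "1")),
      expressed_threshold = as.numeric(cli_flag(args, "expressed-threshold", "0.1")),
      alpha = as.numeric(cli_flag(args, "alpha", "0.05")),
      exclude_xist = "--exclude-xist" %in% args)
    return(invisible(run_pipeline(cfg)))
  }
  if (cmd == "report") return(invisible(write_report(out)))
  stop("unknown subcommand: ", cmd)
}
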