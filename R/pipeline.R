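#' Default pipeline run configuration
#'
#' Nested list consumed by [run_pipeline()]. `synth` holds
#' [synth_config()] arguments; `features` the regression-feature settings;
#' `train` the nested-CV and TPE budget; `evaluate` the metric thresholds
#' and null count; `tissue_spec` the IQR threshold and permutation budget.
#' All stage seeds derive from the single master `seed`.
#'
#' @param seed master seed.
#' @param outdir output directory for stage results.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("tfnetmap_run_")) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    synth = list(),
    features = list(lasso_penalty = "lambda.1se", bart_trees = 50L,
                    bart_depth = 3L),
    train = list(k_outer = 10L, k_inner = 5L, n_trials = 10L,
                 variants = "METANet", tissues = NULL),
    evaluate = list(thresholds = c(25L, 50L), n_null = 50L),
    tissue_spec = list(iqr_threshold = 2, n_perm = 2000L)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. CLI-style overrides can be layered on top.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied last (e.g. `list(seed = 7)`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  merge_into <- function(base, extra) {
    for (nm in names(extra)) {
      if (is.list(extra[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], extra[[nm]])
      } else {
        base[[nm]] <- extra[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) cfg <- merge_into(cfg, yaml::read_yaml(path))
  cfg <- merge_into(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

stage_manifest_path <- function(outdir, stage) {
  file.path(outdir, sprintf("manifest_%s.json", stage))
}

write_stage_manifest <- function(outdir, stage, cfg, files) {
  jsonlite::write_json(
    list(stage = stage, files = files,
         config = jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)),
    stage_manifest_path(outdir, stage), auto_unbox = TRUE, pretty = TRUE)
}

stage_current <- function(outdir, stage, cfg) {
  p <- stage_manifest_path(outdir, stage)
  if (!file.exists(p)) return(FALSE)
  man <- jsonlite::read_json(p)
  identical(as.character(man$config),
            as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))) &&
    all(file.exists(file.path(outdir, unlist(man$files))))
}

#' Run the full network-mapping pipeline
#'
#' Stages, in order: `simulate` (synthetic world), `labels` (q filter,
#' binding scores, binarized labels), `features` (per-tissue five-feature
#' tables), `train` (nested-CV edge scoring per tissue and variant),
#' `evaluate` (binding/GO/GO-directness/PPI metrics at each threshold,
#' plus permuted-null binding metrics), `tissue_spec` (IQR edge filtering
#' and eQTL matching-rank specificity test). Each stage writes its outputs
#' and a manifest under `config$outdir`; with `resume = TRUE` a stage
#' whose manifest matches the current config (and whose predecessors were
#' not re-run) is loaded from disk instead of recomputed.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param resume reuse stage outputs that are already current.
#' @return invisible list with the in-memory stage outputs (`world`,
#'   `labels`, `features`, `networks`, `metrics`, `tissue_spec`).
#' @export
run_pipeline <- function(config = default_run_config(), resume = FALSE) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- sub_seeds(config$seed, 5L)
  dirty <- FALSE
  run_stage <- function(stage, compute, load) {
    if (resume && !dirty && stage_current(outdir, stage, config)) {
      message("[", stage, "] up to date, loading")
      return(load())
    }
    dirty <<- TRUE
    message("[", stage, "] running")
    t0 <- Sys.time()
    out <- tryCatch(compute(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  # -- simulate ------------------------------------------------------------
  world <- run_stage("simulate", compute = function() {
    scfg <- do.call(synth_config, c(config$synth,
                                    list(seed = config$seed)))
    w <- simulate_world(scfg)
    write_world(w, file.path(outdir, "world"))
    write_stage_manifest(outdir, "simulate", config,
                         file.path("world", "world.json"))
    w
  }, load = function() read_world_dir(file.path(outdir, "world")))

  tissues <- names(world$motif_networks)
  use_tissues <- config$train$tissues %||% tissues

  # -- labels --------------------------------------------------------------
  labels <- run_stage("labels", compute = function() {
    lab <- binding_label_matrix(world$peaks, world$elements)
    fwrite(lab$scores, file.path(outdir, "binding_scores.tsv"), sep = "\t")
    fwrite(lab$labels, file.path(outdir, "binding_labels.tsv"), sep = "\t")
    write_stage_manifest(outdir, "labels", config,
                         c("binding_scores.tsv", "binding_labels.tsv"))
    lab
  }, load = function() {
    list(scores = fread(file.path(outdir, "binding_scores.tsv")),
         labels = fread(file.path(outdir, "binding_labels.tsv")))
  })

  # -- features ------------------------------------------------------------
  features <- run_stage("features", compute = function() {
    kept <- filter_low_expression(world$expression)
    tfs <- tf_ids(world$config)
    fseed <- sub_seeds(seeds[1L], 2L)
    ta <- list(
      lasso = lasso_features(world$expression, tfs, genes = kept,
                             penalty = config$features$lasso_penalty,
                             seed = fseed[1L]),
      bart = bart_features(world$expression, tfs, genes = kept,
                           num_trees = config$features$bart_trees,
                           max_depth = config$features$bart_depth,
                           seed = fseed[2L]))
    tabs <- lapply(setNames(use_tissues, use_tissues), function(t) {
      tseed <- sub_seeds(seeds[1L], 2L + 2L * match(t, tissues))
      ts <- list(
        lasso = lasso_features(world$expression, tfs, genes = kept,
                               tissue = t,
                               penalty = config$features$lasso_penalty,
                               seed = tseed[1L]),
        bart = bart_features(world$expression, tfs, genes = kept,
                             tissue = t,
                             num_trees = config$features$bart_trees,
                             max_depth = config$features$bart_depth,
                             seed = tseed[2L]))
      assemble_feature_table(world$motif_networks[[t]], ts, ta,
                             labels$labels, genes = kept, tissue = t)
    })
    for (t in names(tabs)) {
      fwrite(tabs[[t]], file.path(outdir, sprintf("features_%s.tsv", t)),
             sep = "\t")
    }
    write_stage_manifest(outdir, "features", config,
                         sprintf("features_%s.tsv", names(tabs)))
    tabs
  }, load = function() {
    lapply(setNames(use_tissues, use_tissues), function(t) {
      fread(file.path(outdir, sprintf("features_%s.tsv", t)))
    })
  })

  # -- train ---------------------------------------------------------------
  networks <- run_stage("train", compute = function() {
    out <- list()
    files <- character()
    for (t in use_tissues) {
      plan <- make_cv_plan(features[[t]], k_outer = config$train$k_outer,
                           k_inner = config$train$k_inner,
                           seed = seeds[2L] + match(t, tissues))
      for (v in config$train$variants) {
        net <- train_and_score(features[[t]], v, plan,
                               n_trials = config$train$n_trials,
                               seed = seeds[2L] + match(t, tissues))
        out[[paste(v, t, sep = "@")]] <- net
        f <- sprintf("network_%s_%s.tsv", gsub("[^A-Za-z0-9]", "", v), t)
        write_edge_network(net, file.path(outdir, f))
        files <- c(files, f)
      }
    }
    write_stage_manifest(outdir, "train", config, files)
    out
  }, load = function() {
    out <- list()
    for (t in use_tissues) {
      for (v in config$train$variants) {
        f <- sprintf("network_%s_%s.tsv", gsub("[^A-Za-z0-9]", "", v), t)
        out[[paste(v, t, sep = "@")]] <-
          read_edge_network(file.path(outdir, f), tissue = t,
                            semantics = "probability")
      }
    }
    out
  })

  # -- evaluate ------------------------------------------------------------
  metrics <- run_stage("evaluate", compute = function() {
    support <- labels$scores[score > 0, .(tf, gene)]
    universe <- sort(unique(features[[use_tissues[1L]]]$gene))
    rows <- list()
    for (key in names(networks)) {
      net <- networks[[key]]
      parts <- strsplit(key, "@", fixed = TRUE)[[1L]]
      nulls <- permuted_nulls(net, n = config$evaluate$n_null,
                              seed = seeds[3L])
      for (th in config$evaluate$thresholds) {
        topk <- threshold_topk(net, th)
        bm <- binding_metric(topk, support)
        enr <- go_enrichment_score(topk, world$go_map, universe)
        gd <- go_directness(topk, enr, world$go_map, support)
        pm <- ppi_metric(topk, world$ppi)
        null_bind <- vapply(nulls, function(nn) {
          binding_metric(threshold_topk(nn, th), support)$value
        }, 0)
        rows[[length(rows) + 1L]] <- data.table(
          network = parts[1L], tissue = parts[2L], threshold = th,
          metric = c("binding", "go", "go_directness", "ppi",
                     "null_binding_mean", "null_binding_max"),
          value = c(bm$value, enr$score, gd$value, pm$value,
                    mean(null_bind), max(null_bind)),
          random_expectation = c(bm$random_expectation, NA, NA,
                                 pm$random_expectation, NA, NA))
      }
    }
    report <- rbindlist(rows)
    fwrite(report, file.path(outdir, "metrics.tsv"), sep = "\t")
    write_stage_manifest(outdir, "evaluate", config, "metrics.tsv")
    report
  }, load = function() fread(file.path(outdir, "metrics.tsv")))

  # -- tissue_spec ---------------------------------------------------------
  tissue_spec <- run_stage("tissue_spec", compute = function() {
    v <- config$train$variants[1L]
    keys <- paste(v, use_tissues, sep = "@")
    out <- list()
    if (length(use_tissues) >= 2L && all(keys %in% names(networks))) {
      wbt <- rbindlist(lapply(use_tissues, function(t) {
        dt <- as.data.table(networks[[paste(v, t, sep = "@")]])
        dt[, tissue := t]
        dt
      }))
      calls <- iqr_filter(wbt, threshold = config$tissue_spec$iqr_threshold)
      fwrite(calls, file.path(outdir, "tissue_specific_edges.tsv"),
             sep = "\t")
      mm_support <- sapply(use_tissues, function(tn) {  # network tn
        sapply(use_tissues, function(td) {              # tissue td eQTLs
          eqtl_metrics(networks[[paste(v, tn, sep = "@")]],
                       world$eqtls[tissue == td], world$peaks,
                       world$elements)$support
        })
      })
      dimnames(mm_support) <- list(use_tissues, use_tissues)
      sp <- specificity_permutation_test(
        mm_support, n_perm = config$tissue_spec$n_perm, seed = seeds[4L])
      jsonlite::write_json(
        list(S_obs = sp$S_obs, p = sp$p, n_perm = sp$n_perm),
        file.path(outdir, "specificity.json"), auto_unbox = TRUE)
      out <- list(calls = calls, metric_matrix = mm_support,
                  specificity = sp)
      write_stage_manifest(outdir, "tissue_spec", config,
                           c("tissue_specific_edges.tsv",
                             "specificity.json"))
    } else {
      write_stage_manifest(outdir, "tissue_spec", config, character())
    }
    out
  }, load = function() {
    list(calls = fread(file.path(outdir, "tissue_specific_edges.tsv")))
  })

  invisible(list(world = world, labels = labels, features = features,
                 networks = networks, metrics = metrics,
                 tissue_spec = tissue_spec, outdir = outdir))
}

# reload a written world directory
read_world_dir <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "world.json"))
  cfg <- do.call(synth_config, man$config)
  elements <- read_bed_elements(file.path(dir, "elements.bed"))
  peaks <- read_bed_peaks(file.path(dir, "peaks.bed"))
  expr <- read_expression(file.path(dir, "expression_counts.tsv"),
                          file.path(dir, "expression_tpm.tsv"),
                          file.path(dir, "sample_map.tsv"))
  tiss <- tissue_ids(cfg)
  motif_networks <- setNames(lapply(tiss, function(t) {
    read_edge_network(file.path(dir, sprintf("motif_%s.tsv", t)),
                      tissue = t, semantics = "prior")
  }), tiss)
  structure(list(
    config = cfg,
    truth = fread(file.path(dir, "truth.tsv")),
    expression = expr, elements = elements, peaks = peaks,
    motif_networks = motif_networks,
    go_map = read_gmt(file.path(dir, "go_map.gmt")),
    ppi = read_ppi(file.path(dir, "ppi.tsv"), min_score = 0),
    eqtls = read_eqtls(file.path(dir, "eqtls.tsv")),
    seed = cfg$seed), class = "synthetic_world")
}

#' Validate pipeline input files
#'
#' Checks BED coordinate sanity and sortedness, expression/tissue-map
#' consistency and network weight ranges, distinguishing warnings from
#' fatal problems.
#'
#' @param paths named list; recognized names: `elements`, `peaks`,
#'   `counts`, `tpm`, `sample_map`, `networks` (character vector of edge
#'   TSVs tagged as probabilities).
#' @return `data.table` with columns `check`, `level` (`"ok"`,
#'   `"warning"`, `"fatal"`) and `message`.
#' @export
validate_inputs <- function(paths) {
  res <- list()
  note <- function(check, level, message) {
    res[[length(res) + 1L]] <<- data.table(check = check, level = level,
                                           message = message)
  }
  check_bed <- function(path, what) {
    if (!file.exists(path)) {
      note(what, "fatal", paste("missing file:", path))
      return(invisible())
    }
    dt <- fread(path, sep = "\t")
    if (any(dt[[3L]] <= dt[[2L]])) {
      note(what, "fatal", "interval with end <= start")
    } else note(what, "ok", "coordinates valid")
    if (is.unsorted(dt[[2L]])) {
      note(what, "warning", "intervals not sorted by start")
    }
  }
  if (!is.null(paths$elements)) check_bed(paths$elements, "elements")
  if (!is.null(paths$peaks)) check_bed(paths$peaks, "peaks")
  if (!is.null(paths$counts) && !is.null(paths$sample_map)) {
    dt <- fread(paths$counts, sep = "\t")
    sm <- fread(paths$sample_map, sep = "\t")
    missing <- setdiff(colnames(dt)[-1L], sm[[1L]])
    if (length(missing)) {
      note("sample_map", "fatal",
           paste("samples missing from tissue map:",
                 paste(head(missing, 5L), collapse = ", ")))
    } else note("sample_map", "ok", "all samples mapped")
  }
  for (np in paths$networks %||% character()) {
    dt <- fread(np, sep = "\t")
    w <- dt[[3L]]
    if (any(w < 0 | w > 1)) {
      note("network", "fatal",
           paste0(np, ": probability weight outside [0, 1]"))
    } else note("network", "ok", paste0(np, ": weights in range"))
  }
  rbindlist(res)
}
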