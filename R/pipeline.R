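#' Run the full analysis pipeline on a sample table
#'
#' Executes the requested stages in dependency order (io -> correlation /
#' multivariate -> path analysis / color regression -> SEM), writes each
#' stage's output as CSV/JSON under \code{out_dir} and returns a manifest.
#' Identical configuration and seed give identical outputs. Stages whose
#' required variables are absent fail with a descriptive error before
#' anything runs.
#'
#' @param config A list (or path to a YAML/JSON file) with entries:
#'   \code{input} (path to a sample table) or \code{synth = TRUE} (use the
#'   synthetic generator), \code{stages} (subset of \code{"summary"},
#'   \code{"correlate"}, \code{"pca"}, \code{"hca"}, \code{"oplsda"},
#'   \code{"path"}, \code{"regress"}, \code{"sem"}), \code{out_dir},
#'   \code{seed}, and optional stage parameters (\code{pca_scaling},
#'   \code{hca_linkage}, \code{p_enter}, \code{p_remove},
#'   \code{sem_model} text).
#' @return The manifest (list), invisibly written as
#'   \code{manifest.json} too.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) stop("config needs out_dir")
             else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (is.null(config$stages))
    c("summary", "correlate", "pca", "hca", "path", "regress", "sem")
  else config$stages

  if (!is.null(config$input)) {
    if (!file.exists(config$input))
      stop("config error: input file not found: ", config$input)
    tab <- read_sample_table(config$input, config$schema)
    input_desc <- list(path = config$input,
                       checksum = unname(tools::md5sum(config$input)))
  } else if (isTRUE(config$synth)) {
    tab <- generate_samples(default_synth_config(seed = seed))$table
    input_desc <- list(synth = TRUE, seed = seed)
  } else stop("config needs either input or synth = TRUE")

  an <- intersect(analyte_catalog()$code, names(tab))
  cl <- intersect(climate_catalog()$code, names(tab))
  has_color <- all(color_axes() %in% names(tab))
  need <- function(stage, ok, what)
    if (stage %in% stages && !ok)
      stop("stage '", stage, "' requires ", what, " columns, absent from input")
  need("path", length(cl) > 0, "climate")
  need("sem", length(cl) > 0 && has_color, "climate and color")
  need("regress", has_color, "color")

  outputs <- list()
  emit_csv <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    outputs[[name]] <<- basename(path)
  }
  done <- character(0)

  if ("summary" %in% stages) {
    emit_csv("summary_ranges", summarize_ranges(tab, an))
    done <- c(done, "summary")
  }
  if ("correlate" %in% stages) {
    vars <- c(an, if (has_color) color_axes(), cl)
    cr <- pearson_matrix(tab, vars)
    emit_csv("correlations_long", correlation_long(cr))
    done <- c(done, "correlate")
  }
  if ("pca" %in% stages) {
    sc <- if (is.null(config$pca_scaling)) "unit_variance" else config$pca_scaling
    pc <- run_pca(tab, an, scaling = sc)
    emit_csv("pca_explained",
             data.frame(component = names(pc$explained_pct),
                        explained_pct = pc$explained_pct,
                        cumulative_pct = pc$cumulative_pct))
    emit_csv("pca_scores", data.frame(sample_id = rownames(pc$scores),
                                      pc$scores[, 1:min(4, ncol(pc$scores))]))
    done <- c(done, "pca")
  }
  if ("hca" %in% stages) {
    lk <- if (is.null(config$hca_linkage)) "complete" else config$hca_linkage
    hc <- run_hca(tab, an, linkage = lk)
    writeLines(export_newick(hc), file.path(out_dir, "hca_dendrogram.nwk"))
    outputs[["hca_dendrogram"]] <- "hca_dendrogram.nwk"
    done <- c(done, "hca")
  }
  if ("oplsda" %in% stages) {
    classes <- if (!is.null(config$classes)) config$classes
      else if ("group" %in% names(tab) && !is.null(config$high_groups))
        ifelse(tab$group %in% config$high_groups, "high", "low")
      else if ("altitude" %in% names(tab))
        ifelse(tab$altitude > stats::median(tab$altitude), "high", "low")
      else stop("stage 'oplsda' needs classes, high_groups or altitude")
    op <- run_oplsda(tab, an, classes, seed = seed)
    emit_csv("oplsda_scores",
             data.frame(sample_id = names(op$predictive_scores),
                        class = classes, score = op$predictive_scores))
    emit_csv("oplsda_summary",
             data.frame(r2x = op$r2x, r2y = op$r2y, q2 = op$q2))
    done <- c(done, "oplsda")
  }
  if ("path" %in% stages) {
    pe <- if (is.null(config$p_enter)) 0.05 else config$p_enter
    pr <- if (is.null(config$p_remove)) 0.10 else config$p_remove
    responses <- c(an, if (has_color) color_axes())
    rows <- list()
    for (rv in responses) {
      tr <- stepwise_select(tab, rv, cl, pe, pr)
      if (!length(tr$final_set)) next
      pa <- path_decompose(tab, rv, tr$final_set)
      rows[[rv]] <- path_table(pa)[c("response", "factor", "r", "direct",
                                     "indirect_total", "decision", "p")]
    }
    emit_csv("path_analysis", do.call(rbind, c(rows, make.row.names = FALSE)))
    done <- c(done, "path")
  }
  if ("regress" %in% stages) {
    emit_csv("color_regressions", attr(regression_table(tab, an), "summary"))
    done <- c(done, "regress")
  }
  if ("sem" %in% stages) {
    model_txt <- if (!is.null(config$sem_model)) config$sem_model else {
      # default: the two strongest climate factors, one mediator, one axis
      stop("stage 'sem' needs a sem_model text (\"SRC -> DST\" lines)")
    }
    spec <- parse_sem_spec(model_txt)
    fit <- fit_sem(tab, spec)
    emit_csv("sem_edges", sem_edge_table(fit))
    emit_csv("sem_fit_indices",
             data.frame(chi2 = fit$chi2, df = fit$df, cmin_df = fit$cmin_df,
                        rmsea = fit$rmsea, gfi = fit$gfi, agfi = fit$agfi,
                        converged = fit$converged))
    done <- c(done, "sem")
  }

  manifest <- list(package = "peelpath",
                   version = as.character(utils::packageVersion("peelpath")),
                   seed = seed, input = input_desc,
                   stages_requested = stages, stages_completed = done,
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Assemble a plain-text report from a pipeline run directory
#'
#' Collects the correlation, path-analysis, color-regression, SEM and
#' PCA/HCA outputs written by [run_pipeline()] into one human-readable
#' document; stages missing from the manifest are noted as gaps.
#'
#' @param run_dir Directory containing \code{manifest.json}.
#' @param path Optional output path; default \code{report.txt} inside
#'   \code{run_dir}.
#' @return The report path, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.txt")) {
  mf <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf)) stop("manifest.json not found in ", run_dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  con <- textConnection("rpt", "w", local = TRUE)
  w <- function(...) writeLines(paste0(...), con)
  w("Climate-flavonoid-peel-color pipeline report")
  w("=============================================")
  w("seed: ", manifest$seed, "   stages: ",
    paste(manifest$stages_completed, collapse = ", "))
  section <- function(title, file, reader = utils::read.csv) {
    w(""); w(title); w(strrep("-", nchar(title)))
    fp <- file.path(run_dir, file)
    if (file.exists(fp)) {
      out <- utils::capture.output(print(reader(fp), digits = 4))
      writeLines(out, con)
    } else w("[stage not run - gap]")
  }
  section("Per-analyte ranges", "summary_ranges.csv")
  section("Pairwise correlations (long form)", "correlations_long.csv")
  section("PCA explained variance", "pca_explained.csv")
  section("HCA dendrogram (newick)", "hca_dendrogram.nwk", readLines)
  section("Path analysis (direct/indirect/decision)", "path_analysis.csv")
  section("Content-on-color regressions", "color_regressions.csv")
  section("SEM standardized edges", "sem_edges.csv")
  section("SEM fit indices", "sem_fit_indices.csv")
  gaps <- setdiff(manifest$stages_requested, manifest$stages_completed)
  if (length(gaps)) { w(""); w("Gaps: ", paste(gaps, collapse = ", ")) }
  close(con)
  writeLines(rpt, path)
  invisible(path)
}
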