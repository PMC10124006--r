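#' Read a pipeline configuration from YAML
#'
#' The configuration names the input files and the analysis parameters.
#' Recognized keys: `gtf`, `stage_counts`, `counts_a`, `counts_b`,
#' `lengths`, `fractions`, `groups`, `de_tables` (list of paths),
#' `window_nt`, `p_max`, `lfc_min`, `pseudocount`, `min_fpkm`, `top_k`,
#' `seed`, `pcg_biotypes`, `lnc_biotypes`. Unset analysis parameters fall
#' back to the package defaults; unset input paths switch the
#' corresponding stage off. Relative paths are resolved against the
#' config file's directory.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  path_keys <- c("gtf", "stage_counts", "counts_a", "counts_b", "lengths",
                 "fractions", "groups")
  for (k in path_keys) {
    if (!is.null(raw[[k]]) && !grepl("^/", raw[[k]])) {
      raw[[k]] <- file.path(base_dir, raw[[k]])
    }
  }
  if (!is.null(raw$de_tables)) {
    raw$de_tables <- vapply(raw$de_tables, function(p) {
      if (!grepl("^/", p)) file.path(base_dir, p) else p
    }, character(1))
  }
  pipeline_config(raw)
}

#' Build a pipeline configuration from a list
#'
#' @param x Named list of configuration entries (see
#'   [read_pipeline_config()] for recognized keys).
#' @return A named list of class `pipeline_config` with defaults filled
#'   in.
#' @export
pipeline_config <- function(x = list()) {
  defaults <- list(
    gtf = NULL, stage_counts = NULL, counts_a = NULL, counts_b = NULL,
    lengths = NULL, fractions = NULL, groups = NULL, de_tables = NULL,
    window_nt = 50000, p_max = 0.05, lfc_min = 1.0,
    pseudocount = 0.01, min_fpkm = 0.5, top_k = 8, seed = 1L,
    pcg_biotypes = "protein_coding",
    lnc_biotypes = gencode_lnc_biotypes()
  )
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, x)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full characterization workflow
#'
#' Executes the stages in order — positional classification, TPM
#' normalization, localization index, specificity scoring, differential
#' expression and the category breakdown of the calls — skipping any
#' stage whose inputs are not configured. Each stage writes one TSV into
#' `out_dir`; a JSON manifest records package and R versions, the full
#' parameter set, input checksums and the output files, which is enough
#' to reproduce the run. Output TSVs are deterministic given the same
#' config and inputs.
#'
#' @param config A [pipeline_config()] (or list coercible to one).
#' @param out_dir Output directory, created if needed.
#' @return Named list of in-memory stage results, invisibly; side effect
#'   is the TSV/manifest bundle in `out_dir`.
#' @export
run_characterization <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(config$gtf, config$stage_counts, config$counts_a,
              config$counts_b, config$lengths, config$fractions,
              config$groups, config$de_tables)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stop("configured input file(s) not found: ",
         paste(missing, collapse = ", "))
  }
  results <- list()
  st <- new.env(parent = emptyenv())
  st$outputs <- character()
  st$tpm <- NULL
  st$de_tables <- list()
  stage <- function(name, expr) {
    message(sprintf("[lncdesert] stage %-12s ...", name), appendLF = FALSE)
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      message(" failed")
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf(" done (%.2fs)", proc.time()[["elapsed"]] - t0))
    val
  }

  if (!is.null(config$gtf)) {
    results$classification <- stage("classify", {
      annot <- read_gtf(config$gtf, config$pcg_biotypes, config$lnc_biotypes)
      cl <- classify_lncrnas(annot, window_nt = config$window_nt)
      f <- file.path(out_dir, "classification.tsv")
      write_tsv_plain(cl, f)
      prop <- category_proportions(cl)
      write_tsv_plain(data.frame(category = names(prop),
                                 fraction = as.numeric(prop),
                                 percent = sprintf("%.2f", 100 * prop)),
                      file.path(out_dir, "category_proportions.tsv"))
      st$outputs <- c(st$outputs, f,
                      file.path(out_dir, "category_proportions.tsv"))
      cl
    })
  }

  if (!is.null(config$stage_counts)) {
    results$tpm <- stage("normalize", {
      counts <- read_expression_tsv(config$stage_counts, unit = "counts",
                                    lengths_path = config$lengths)
      tpm <- counts_to_tpm(counts)
      f <- file.path(out_dir, "tpm.tsv")
      write_expression_tsv(tpm, f)
      st$outputs <- c(st$outputs, f)
      st$tpm <- tpm
      tpm
    })
  }

  if (!is.null(config$fractions)) {
    results$rci <- stage("rci", {
      frac <- read_tsv_plain(config$fractions)
      rci <- compute_rci(frac, pseudocount = config$pseudocount,
                         min_fpkm = config$min_fpkm)
      f <- file.path(out_dir, "rci.tsv")
      write_tsv_plain(rci, f)
      st$outputs <- c(st$outputs, f)
      if (!is.null(results$classification)) {
        lnc_rci <- rci[rci$gene_id %in% results$classification$gene_id, ]
        tests <- compare_rci_by_category(lnc_rci, results$classification,
                                         pcg_rci = rci[!rci$gene_id %in%
                                                         results$classification$gene_id, ])
        ft <- file.path(out_dir, "rci_category_tests.tsv")
        write_tsv_plain(tests, ft)
        st$outputs <- c(st$outputs, ft)
      }
      rci
    })
  }

  if (!is.null(config$groups) && !is.null(st$tpm)) {
    results$specificity <- stage("specificity", {
      gmap <- read_tsv_plain(config$groups)
      if (!all(c("sample_id", "group") %in% names(gmap))) {
        stop("groups TSV must have columns sample_id and group")
      }
      map <- stats::setNames(gmap$group, gmap$sample_id)
      prof <- stage_means(st$tpm, map)
      sc <- specificity_scores(prof)
      f <- file.path(out_dir, "specificity.tsv")
      write_tsv_plain(sc, f)
      rk <- group_expression_ranking(st$tpm, map, top_k = config$top_k)
      fr <- file.path(out_dir, "group_ranking.tsv")
      write_tsv_plain(rk, fr)
      st$outputs <- c(st$outputs, f, fr)
      sc
    })
  }

  if (!is.null(config$counts_a) && !is.null(config$counts_b)) {
    results$de <- stage("differential", {
      ca <- read_expression_tsv(config$counts_a, unit = "counts",
                                lengths_path = config$lengths)
      cb <- read_expression_tsv(config$counts_b, unit = "counts",
                                lengths_path = config$lengths)
      tab <- simple_de(ca, cb)
      st$de_tables[["simple_de"]] <- tab
      tab
    })
  }
  if (!is.null(config$de_tables)) {
    for (p in config$de_tables) {
      st$de_tables[[basename(p)]] <- de_table(read_tsv_plain(p),
                                              method = paste0("imported:",
                                                              basename(p)))
    }
  }
  if (length(st$de_tables) > 0) {
    results$de_calls <- stage("de_filter", {
      calls <- lapply(st$de_tables, de_filter,
                      p_max = config$p_max, lfc_min = config$lfc_min)
      for (nm in names(calls)) {
        f <- file.path(out_dir, paste0("de_calls_", nm, ".tsv"))
        write_tsv_plain(calls[[nm]], f)
        st$outputs <- c(st$outputs, f)
      }
      calls
    })
    if (!is.null(results$classification)) {
      results$de_breakdown <- stage("de_breakdown", {
        bds <- lapply(results$de_calls, function(calls) {
          lnc_calls <- calls[calls$gene_id %in%
                               results$classification$gene_id, ]
          if (!any(lnc_calls$passed)) return(NULL)
          de_category_breakdown(lnc_calls, results$classification)
        })
        bds <- Filter(Negate(is.null), bds)
        if (length(bds) > 0) {
          avg <- macro_average_breakdown(bds)
          f <- file.path(out_dir, "de_category_breakdown.tsv")
          write_tsv_plain(avg, f)
          st$outputs <- c(st$outputs, f)
        }
        bds
      })
    }
  }

  manifest <- list(
    package = "lncdesert",
    package_version = as.character(utils::packageVersion("lncdesert")),
    r_version = as.character(getRversion()),
    parameters = config[c("window_nt", "p_max", "lfc_min", "pseudocount",
                          "min_fpkm", "top_k", "seed")],
    pcg_biotypes = config$pcg_biotypes,
    lnc_biotypes = config$lnc_biotypes,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = basename(st$outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
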