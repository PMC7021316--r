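#' Run configuration
#'
#' File-level runs are driven by a YAML configuration with up to four
#' blocks: `simulate` (cohort and image generator parameters), `quantify`
#' (detection and QC thresholds plus input paths), `analyze` (ratio factors
#' and optional inline/CSV contingency tables), and `paths` (output
#' directory). `read_run_config()` parses and validates before any
#' computation; unknown keys and malformed values raise config errors, so
#' typos fail fast. Every artifact written by the `run_*` entry points
#' embeds the seed and an MD5 hash of the canonicalized configuration, so
#' two runs with equal hashes are comparable.
#'
#' @param path YAML file path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a raw config list.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) abort_config("config must be a mapping")
  known <- c("simulate", "quantify", "analyze", "paths", "seed")
  bad <- setdiff(names(config), known)
  if (length(bad))
    abort_config(sprintf("unknown config keys: %s (known: %s)",
                         paste(bad, collapse = ", "),
                         paste(known, collapse = ", ")))
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || length(config$seed) != 1L))
    abort_config("seed must be a single integer")
  num_keys <- list(
    simulate = c("images_per_sample", "housekeeping_per_image_mean",
                 "failure_rate", "ratio_floor"),
    quantify = c("sensitivity", "min_area", "max_area", "min_housekeeping",
                 "a_threshold", "background_fraction", "min_valid_images"))
  for (blk in names(num_keys)) {
    for (k in intersect(names(config[[blk]]), num_keys[[blk]])) {
      v <- config[[blk]][[k]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        abort_config(sprintf("%s.%s must be a single finite number", blk, k))
    }
  }
  if (!is.null(config$simulate$groups)) {
    g <- config$simulate$groups
    if (!is.list(g) || !length(g))
      abort_config("simulate.groups must be a nonempty list")
  }
  structure(config, class = c("run_config", "list"))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 12,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Pipeline entry points: simulate, quantify, analyze
#'
#' `run_simulate()` materializes a synthetic cohort on disk: cohort
#' `metadata.csv`, per-image `counts.csv` (count mode) or PNG
#' images/masks plus a per-dot `ground_truth.csv` and per-image
#' `truth_summary.csv` (image mode), and a `manifest.json` echoing seed,
#' parameters and config hash. `run_quantify()` quantifies a simulated (or
#' on-disk) cohort into `cohort.csv` + `exclusions.csv`; a missing mask
#' flags the sample and the run continues. `run_analyze()` produces the
#' summary-table and contingency-table analyses: the ratio against each
#' requested factor with the level-appropriate test, the Bonferroni
#' post-hoc block for the IHC-score factor, and Fisher tests of the binary
#' staining-pattern split (1+ vs 2+/3+) against the clinical factors;
#' results land in `results.csv` and `report.md`.
#'
#' @param config a [validate_config()] list (or path to YAML).
#' @param out_dir output directory, created if needed.
#' @param seed overrides `config$seed`.
#' @return `run_simulate()`: the manifest list, invisibly.
#' @export
run_simulate <- function(config, out_dir = config$paths$out_dir, seed = NULL) {
  config <- ensure_config(config)
  if (is.null(out_dir)) abort_config("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_data(sprintf("cannot create %s", out_dir))
  seed <- if (!is.null(seed)) seed else if (!is.null(config$seed)) config$seed else 1L
  cp <- cohort_params_from_config(config$simulate, seed = seed)
  co <- generate_cohort(cp)
  meta_path <- file.path(out_dir, "metadata.csv")
  write.csv(co$metadata, meta_path, row.names = FALSE)
  if (cp$rendering_mode == "count") {
    counts <- do.call(rbind, lapply(names(co$samples), function(id)
      cbind(sample_id = id, co$samples[[id]])))
    write.csv(counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
  } else {
    img_dir <- file.path(out_dir, "images")
    mask_dir <- file.path(out_dir, "masks")
    dir.create(img_dir, showWarnings = FALSE)
    dir.create(mask_dir, showWarnings = FALSE)
    dots <- list(); summ <- list()
    for (id in names(co$samples)) {
      for (j in seq_along(co$samples[[id]])) {
        iid <- sprintf("%s_img%02d", id, j)
        g <- co$samples[[id]][[j]]
        write_image_png(g$image, file.path(img_dir, paste0(iid, ".png")))
        write_mask_png(g$truth$roi_mask, file.path(mask_dir, paste0(iid, ".png")))
        dots[[iid]] <- rbind(
          centers_df(iid, "target", g$truth$target_centers),
          centers_df(iid, "housekeeping", g$truth$housekeeping_centers))
        summ[[iid]] <- data.frame(
          image_id = iid, sample_id = id,
          true_target_count = g$truth$true_target_count,
          true_housekeeping_count = g$truth$true_housekeeping_count,
          true_ratio = g$truth$true_ratio)
      }
    }
    write.csv(do.call(rbind, dots), file.path(out_dir, "ground_truth.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, summ), file.path(out_dir, "truth_summary.csv"),
              row.names = FALSE)
  }
  manifest <- list(seed = seed, config_hash = config_hash(config),
                   rendering_mode = cp$rendering_mode,
                   n_samples = nrow(co$metadata),
                   images_per_sample = cp$images_per_sample,
                   params = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}

#' @rdname run_simulate
#' @param in_dir directory holding a simulated cohort (defaults to
#'   `out_dir`).
#' @return `run_quantify()`: list with `table` and `exclusions`
#'   data.frames, invisibly.
#' @export
run_quantify <- function(config, in_dir = config$paths$out_dir,
                         out_dir = in_dir) {
  config <- ensure_config(config)
  if (is.null(in_dir)) abort_config("no input directory configured")
  meta_path <- file.path(in_dir, "metadata.csv")
  if (!file.exists(meta_path))
    abort_data(sprintf("no metadata.csv under %s", in_dir))
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  qc <- qc_from_config(config$quantify)
  cfg_t <- det_from_config(config$quantify, "dark")
  cfg_h <- det_from_config(config$quantify, "bright")
  counts_path <- file.path(in_dir, "counts.csv")
  problems <- character(0)
  samples <- vector("list", nrow(meta))
  if (file.exists(counts_path)) {
    counts <- read.csv(counts_path, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(meta))) {
      id <- meta$sample_id[i]
      rows <- counts[counts$sample_id == id, , drop = FALSE]
      quants <- lapply(seq_len(nrow(rows)), function(j) {
        flags <- if (rows$n_housekeeping[j] < qc$min_housekeeping)
          "red_failure" else character(0)
        image_quant(sprintf("%s_img%02d", id, j), rows$n_target[j],
                    rows$n_housekeeping[j], qc_flags = flags)
      })
      samples[[i]] <- aggregate_sample(quants, metadata = meta[i, ],
                                       sample_id = id, qc = qc)
    }
  } else {
    img_dir <- file.path(in_dir, "images")
    if (!dir.exists(img_dir) || !length(list.files(img_dir)))
      abort_data(sprintf("no counts.csv and no images under %s", in_dir))
    for (i in seq_len(nrow(meta))) {
      id <- meta$sample_id[i]
      quants <- list()
      for (j in seq_len(meta$n_images[i])) {
        iid <- sprintf("%s_img%02d", id, j)
        ip <- file.path(img_dir, paste0(iid, ".png"))
        mp <- file.path(in_dir, "masks", paste0(iid, ".png"))
        if (!file.exists(ip) || !file.exists(mp)) {
          problems <- c(problems, iid)
          next
        }
        q <- quantify_image(read_image_png(ip), read_mask_png(mp),
                            cfg_t, cfg_h, qc, image_id = iid)
        message(sprintf("INFO %s: target=%d housekeeping=%d%s", iid,
                        q$n_target, q$n_housekeeping,
                        if (length(q$qc_flags))
                          paste0(" flags=", paste(q$qc_flags, collapse = "+"))
                        else ""))
        quants[[length(quants) + 1L]] <- q
      }
      samples[[i]] <- if (length(quants))
        aggregate_sample(quants, metadata = meta[i, ], sample_id = id, qc = qc)
      else structure(list(sample_id = id, ish_ratio = NA_real_,
                          n_images_used = 0L, excluded = TRUE,
                          reason = "missing_files",
                          metadata = as.list(meta[i, ])),
                     class = "sample_quant")
    }
    if (length(problems))
      message(sprintf("WARN %d image/mask pairs missing: %s",
                      length(problems), paste(problems, collapse = ", ")))
  }
  res <- build_cohort_table(samples)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$table, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    write.csv(res$exclusions, file.path(out_dir, "exclusions.csv"),
              row.names = FALSE)
  }
  invisible(res)
}

#' @rdname run_simulate
#' @param cohort cohort data.frame or path to `cohort.csv`; defaults to the
#'   one under `out_dir`.
#' @param ratio_factors columns to test the ratio against.
#' @param group_factor the ordinal factor given the post-hoc block.
#' @return `run_analyze()`: list with `results` (tidy data.frame: method,
#'   factor, levels, statistic, df, p_raw, p_corrected) and `report`
#'   (character vector of Markdown lines), invisibly.
#' @export
run_analyze <- function(config, cohort = NULL,
                        ratio_factors = c("group", "diagnosis", "grade",
                                          "lymphatic_invasion"),
                        group_factor = "group",
                        out_dir = config$paths$out_dir) {
  config <- ensure_config(config)
  if (is.null(cohort)) cohort <- file.path(out_dir, "cohort.csv")
  if (is.character(cohort)) {
    if (!file.exists(cohort)) abort_data(sprintf("cohort table not found: %s",
                                                 cohort))
    cohort <- read.csv(cohort, stringsAsFactors = FALSE)
  }
  az <- config$analyze
  if (!is.null(az$ratio_factors)) ratio_factors <- unlist(az$ratio_factors)
  for (f in ratio_factors)
    if (!f %in% names(cohort))
      abort_config(sprintf("unknown factor '%s'; available: %s", f,
                           paste(names(cohort), collapse = ", ")))
  rows <- list(); report <- c("# Cohort analysis", "")
  add <- function(method, factor, levels, statistic, df, p_raw,
                  p_corrected = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, factor = factor, levels = levels,
      statistic = statistic, df = df, p_raw = p_raw,
      p_corrected = p_corrected)
  }

  report <- c(report, "## ISH ratio by factor", "")
  for (f in ratio_factors) {
    lv <- unique(stats::na.omit(cohort[[f]]))
    if (length(lv) < 2L) next
    s <- summarize_cohort(cohort, f)
    add(s$test$method, f, nrow(s$summaries),
        unname(s$test$statistic[1]),
        if (!is.null(s$test$parameter)) unname(s$test$parameter[1]) else NA,
        s$test$p.value)
    report <- c(report, sprintf("### %s", f),
                summary_md(s), sprintf("- %s: p = %.4g", s$test$method,
                                       s$test$p.value), "")
  }

  lv <- unique(stats::na.omit(cohort[[group_factor]]))
  if (length(lv) >= 3L) {
    groups <- split(cohort$ish_ratio[!is.na(cohort[[group_factor]])],
                    cohort[[group_factor]][!is.na(cohort[[group_factor]])])
    ph <- posthoc_pairwise(groups)
    for (i in seq_len(nrow(ph)))
      add("pairwise Mann-Whitney U (Bonferroni)", group_factor,
          paste(ph$group1[i], ph$group2[i], sep = " vs "),
          ph$U[i], NA, ph$p_raw[i], ph$p_adj[i])
    report <- c(report, sprintf("## Post-hoc (%s, Bonferroni)", group_factor),
                utils::capture.output(print.data.frame(ph, row.names = FALSE)),
                "")
  }

  # binary staining-pattern split vs clinical factors, exact tests
  if ("group" %in% names(cohort)) {
    pattern <- ifelse(cohort$group == "1+", "incomplete", "complete")
    for (f in setdiff(ratio_factors, "group")) {
      tb <- table(cohort[[f]], pattern)
      if (nrow(tb) < 2L || ncol(tb) < 2L) next
      ct <- contingency_table(unclass(tb))
      r <- if (all(dim(ct) == 2L)) fisher_exact_2x2(ct)
           else fisher_freeman_halton(ct)
      add(r$method, f, paste(dim(ct), collapse = "x"), NA, NA, r$p.value)
      report <- c(report,
                  sprintf("- %s vs staining pattern: %s, p = %.4g", f,
                          r$method, r$p.value))
    }
  }

  # user-supplied contingency tables (inline counts or CSV files)
  for (ctab in az$contingency) {
    ct <- contingency_from_config(ctab)
    r <- if (all(dim(ct) == 2L)) fisher_exact_2x2(ct)
         else fisher_freeman_halton(ct)
    add(r$method, ctab$name %||% "contingency",
        paste(dim(ct), collapse = "x"), NA, NA, r$p.value)
    report <- c(report, sprintf("- %s: %s, p = %.4g",
                                ctab$name %||% "contingency", r$method,
                                r$p.value))
  }

  results <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    writeLines(report, file.path(out_dir, "report.md"))
  }
  invisible(list(results = results, report = report))
}

summary_md <- function(s) {
  df <- s$summaries
  c(sprintf("- %s (n = %d): %.3f +/- %.3f", df$group, df$n, df$mean, df$sd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ensure_config <- function(config) {
  if (is.character(config)) return(read_run_config(config))
  if (!inherits(config, "run_config")) return(validate_config(config))
  config
}

cohort_params_from_config <- function(sim, seed) {
  sim <- sim %||% list()
  groups <- if (!is.null(sim$groups))
    do.call(rbind, lapply(sim$groups, as.data.frame))
  else default_cohort_groups()
  img <- do.call(image_params, sim$image %||% list(height = 256L, width = 256L))
  cohort_params(
    groups = groups,
    images_per_sample = sim$images_per_sample %||% 5L,
    housekeeping_per_image_mean = sim$housekeeping_per_image_mean %||% 25,
    rendering_mode = sim$rendering_mode %||% "count",
    failure_rate = sim$failure_rate %||% 0,
    ratio_floor = sim$ratio_floor %||% 0.1,
    image = img, seed = seed)
}

det_from_config <- function(q, mode) {
  q <- q %||% list()
  detection_config(mode = mode, scales = q$scales %||% 2L,
                   sensitivity = q$sensitivity %||% 2.0,
                   min_area = q$min_area %||% 4L,
                   max_area = q$max_area %||% 2000L)
}

qc_from_config <- function(q) {
  q <- q %||% list()
  quant_config(min_housekeeping = q$min_housekeeping %||% 5L,
               a_threshold = q$a_threshold %||% 10,
               background_fraction = q$background_fraction %||% 0.25,
               min_valid_images = q$min_valid_images %||% 3L)
}

contingency_from_config <- function(ctab) {
  if (!is.null(ctab$file)) {
    m <- as.matrix(read.csv(ctab$file, header = FALSE))
  } else if (!is.null(ctab$counts)) {
    m <- do.call(rbind, lapply(ctab$counts, unlist))
  } else abort_config("contingency entry needs 'file' or 'counts'")
  contingency_table(m)
}

centers_df <- function(image_id, channel, centers) {
  if (nrow(centers) == 0L)
    return(data.frame(image_id = character(0), channel = character(0),
                      row = numeric(0), col = numeric(0)))
  data.frame(image_id = image_id, channel = channel,
             row = centers[, 1L], col = centers[, 2L])
}
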