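#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline with validated
#' defaults. `populations` maps population labels to their input files:
#' each entry is a list with `nuclear`, `protein` and `selections` paths.
#' The configuration serializes losslessly to JSON via
#' [write_run_config()] / [read_run_config()].
#'
#' @param populations Named list of input path lists (may be empty when
#'   the configuration is only used for stage functions).
#' @param reference Reference population label for comparisons.
#' @param out_dir Output directory for persisted intermediates.
#' @param min_area,smoothing_sigma,seed_separation Nucleus segmentation
#'   parameters (px^2 / px / px).
#' @param max_snap_distance Selection-to-nucleus snap distance (px).
#' @param step_px Profile sampling step (px).
#' @param L Normalized profile length (samples).
#' @param n_angles Radial profiles per cell.
#' @param ray_length Radial ray length (px).
#' @param denoise_strength TV weight in the Anscombe domain.
#' @param warp_knots,max_shift,smooth_weight,tol,max_iter Geometric
#'   compensation parameters.
#' @param rd_align_angles Align the per-angle mean radial profiles with a
#'   second compensation pass before virtual-cell reconstruction.
#' @param membrane_window Membrane window half-width (normalized units).
#' @param alpha Family-wise significance level.
#' @param exact_max_n Exact Mann-Whitney enumeration limit.
#' @param low_pct,high_pct Contrast-enhancement percentiles.
#' @param seed Global seed; per-stage sub-seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(populations = list(), reference = "WT",
                       out_dir = tempfile("profilecad_run"),
                       min_area = 30, smoothing_sigma = 1,
                       seed_separation = 5, max_snap_distance = 10,
                       step_px = 1, L = 100L, n_angles = 36L,
                       ray_length = 60,
                       denoise_strength = 2, warp_knots = 5L,
                       max_shift = 0.15, smooth_weight = 0.01,
                       tol = 1e-4, max_iter = 50L,
                       rd_align_angles = TRUE,
                       membrane_window = 0.05, alpha = 0.05,
                       exact_max_n = 8L, low_pct = 1, high_pct = 99,
                       seed = 1L) {
  cfg <- list(
    populations = populations, reference = reference, out_dir = out_dir,
    min_area = min_area, smoothing_sigma = smoothing_sigma,
    seed_separation = seed_separation,
    max_snap_distance = max_snap_distance,
    step_px = step_px, L = as.integer(L),
    n_angles = as.integer(n_angles), ray_length = ray_length,
    denoise_strength = denoise_strength,
    warp_knots = as.integer(warp_knots), max_shift = max_shift,
    smooth_weight = smooth_weight, tol = tol,
    max_iter = as.integer(max_iter),
    rd_align_angles = isTRUE(rd_align_angles),
    membrane_window = membrane_window, alpha = alpha,
    exact_max_n = as.integer(exact_max_n),
    low_pct = low_pct, high_pct = high_pct, seed = as.integer(seed)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(
    cfg$min_area >= 0, cfg$smoothing_sigma >= 0,
    cfg$seed_separation >= 1, cfg$max_snap_distance >= 0,
    cfg$step_px > 0, cfg$L >= 2, cfg$n_angles >= 4, cfg$ray_length > 0,
    cfg$denoise_strength >= 0, cfg$warp_knots >= 1,
    cfg$max_shift > 0, cfg$max_shift < 0.5, cfg$smooth_weight >= 0,
    cfg$tol > 0, cfg$max_iter >= 1,
    cfg$membrane_window > 0, cfg$membrane_window < 0.5,
    cfg$alpha > 0, cfg$alpha < 1, cfg$exact_max_n >= 1,
    cfg$low_pct < cfg$high_pct
  )
  invisible(cfg)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$populations <- lapply(raw$populations, as.list)
  do.call(run_config, raw)
}

#' Read / write a cell-selection CSV
#'
#' Dialect: header `type,image_id,row1,col1,row2,col2`; `type` is
#' `point` (single nucleus, `row2`/`col2` empty) or `pair` (two nuclei);
#' coordinates are 0-based pixel positions. Malformed rows are reported
#' with their line numbers.
#'
#' @param path CSV path.
#' @return Tibble of selections.
#' @export
read_selection_csv <- function(path) {
  df <- readr::read_csv(path, col_types = "ccdddd")
  required <- c("type", "image_id", "row1", "col1", "row2", "col2")
  if (!all(required %in% names(df))) {
    stop("read_selection_csv: header must contain ",
         paste(required, collapse = ","), call. = FALSE)
  }
  bad_type <- which(!df$type %in% c("point", "pair"))
  bad_point <- which(df$type == "point" &
                       (is.na(df$row1) | is.na(df$col1)))
  bad_pair <- which(df$type == "pair" &
                      (is.na(df$row1) | is.na(df$col1) |
                         is.na(df$row2) | is.na(df$col2)))
  bad <- sort(unique(c(bad_type, bad_point, bad_pair)))
  if (length(bad) > 0) {
    stop("read_selection_csv: malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  df
}

#' @rdname read_selection_csv
#' @param selections Tibble with the dialect columns.
#' @export
write_selection_csv <- function(selections, path) {
  required <- c("type", "image_id", "row1", "col1", "row2", "col2")
  stopifnot(all(required %in% names(selections)))
  readr::write_csv(selections[required], path, na = "")
  invisible(path)
}

# Deterministic per-stage sub-seed from the global seed (kept < 2^31).
derive_seed <- function(seed, stage) {
  h <- rlang::hash(list(seed = as.integer(seed), stage = stage))
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

#' Process one population end to end
#'
#' Runs segmentation, selection matching, IN profile extraction and
#' normalization, map building, denoising, geometric compensation,
#' averaging and feature computation for a single population; optionally
#' extracts RD profiles from the `point` selections and reconstructs the
#' population's virtual cell.
#'
#' @param nuclear,protein [channel_image()]s.
#' @param selections Selection tibble ([read_selection_csv()]).
#' @param config A [run_config()].
#' @param rd Also compute RD profiles and the virtual cell.
#' @return List: `label_map`, `matches`, `in_map_raw`, `in_map`,
#'   `average_profile`, `features`, `virtual_cell` (or NULL), `log`
#'   (tibble of counts: selections used / excluded and why).
#' @export
process_population <- function(nuclear, protein, selections, config,
                               rd = TRUE) {
  lm <- segment_nuclei(nuclear, min_area = config$min_area,
                       smoothing_sigma = config$smoothing_sigma,
                       seed_separation = config$seed_separation)
  log <- list()
  note <- function(stage, n, why) {
    tibble::tibble(stage = stage, count = as.integer(n), detail = why)
  }

  pairs <- selections[selections$type == "pair", , drop = FALSE]
  points <- selections[selections$type == "point", , drop = FALSE]
  log$pairs_in <- note("selection", nrow(pairs), "pair rows read")
  log$points_in <- note("selection", nrow(points), "point rows read")

  # ---- IN profiles from pair selections -------------------------------
  in_profiles <- list(); n_excluded_pair <- 0L
  if (nrow(pairs) > 0) {
    m1 <- suppressWarnings(
      match_selection(lm, data.frame(row = pairs$row1, col = pairs$col1),
                      config$max_snap_distance))
    m2 <- suppressWarnings(
      match_selection(lm, data.frame(row = pairs$row2, col = pairs$col2),
                      config$max_snap_distance))
    for (i in seq_len(nrow(pairs))) {
      if (!m1$matched[i] || !m2$matched[i] ||
          m1$label[i] == m2$label[i]) {
        n_excluded_pair <- n_excluded_pair + 1L
        next
      }
      c1 <- unlist(lm$nuclei[lm$nuclei$label == m1$label[i],
                             c("row", "col")])
      c2 <- unlist(lm$nuclei[lm$nuclei$label == m2$label[i],
                             c("row", "col")])
      p <- tryCatch(
        extract_in_profile(protein, c1, c2, step_px = config$step_px,
                           source_id = paste0("pair_", i)),
        error = function(e) NULL)
      if (is.null(p)) {
        n_excluded_pair <- n_excluded_pair + 1L
      } else {
        in_profiles[[length(in_profiles) + 1L]] <- p
      }
    }
  }
  log$pairs_used <- note("in_profiles", length(in_profiles), "pairs used")
  log$pairs_excl <- note("in_profiles", n_excluded_pair,
                         "pairs excluded (unmatched, duplicate or out of bounds)")

  in_map_raw <- NULL; in_map <- NULL; avg <- NULL; features <- NULL
  if (length(in_profiles) > 0) {
    normed <- lapply(in_profiles, normalize_length, L = config$L)
    in_map_raw <- build_map(normed)
    dn <- denoise_map(in_map_raw, strength = config$denoise_strength)
    in_map <- if (ncol(dn$values) >= 2L) {
      compensate_map(dn, max_iter = config$max_iter, tol = config$tol,
                     warp_knots = config$warp_knots,
                     max_shift = config$max_shift,
                     smooth_weight = config$smooth_weight)
    } else dn
    avg <- summarize_map(in_map)
    features <- profile_features(in_map, window = config$membrane_window)
  }

  # ---- RD profiles and virtual cell from point selections -------------
  vc <- NULL; rd_excluded <- 0L
  if (rd && nrow(points) > 0) {
    mp <- suppressWarnings(
      match_selection(lm, data.frame(row = points$row1, col = points$col1),
                      config$max_snap_distance))
    per_angle <- vector("list", config$n_angles)
    for (i in which(mp$matched)) {
      cen <- unlist(lm$nuclei[lm$nuclei$label == mp$label[i],
                              c("row", "col")])
      prof <- tryCatch(
        extract_rd_profiles(protein, cen, n_angles = config$n_angles,
                            ray_length = config$ray_length,
                            step_px = config$step_px,
                            source_id = paste0("cell_", i)),
        error = function(e) list())
      rd_excluded <- rd_excluded + length(attr(prof, "excluded_angles"))
      kept_angles <- attr(prof, "kept_k")
      for (kk in seq_along(prof)) {
        k <- kept_angles[kk] + 1L
        per_angle[[k]] <- c(per_angle[[k]],
                            list(normalize_length(prof[[kk]], L = config$L)))
      }
    }
    angle_means <- lapply(per_angle, function(ps) {
      if (is.null(ps)) return(NULL)
      m <- build_map(ps)
      if (ncol(m$values) >= 2L) {
        m <- compensate_map(m, max_iter = config$max_iter,
                            tol = config$tol,
                            warp_knots = config$warp_knots,
                            max_shift = config$max_shift,
                            smooth_weight = config$smooth_weight)
      }
      rowMeans(m$values)
    })
    keep <- !vapply(angle_means, is.null, logical(1))
    if (sum(keep) >= 4L) {
      polar <- do.call(rbind, angle_means[keep])
      if (config$rd_align_angles && nrow(polar) >= 2L) {
        am <- compensate_map(build_map(t(polar)),
                             max_iter = config$max_iter, tol = config$tol,
                             warp_knots = config$warp_knots,
                             max_shift = config$max_shift,
                             smooth_weight = config$smooth_weight)
        polar <- t(am$values)
      }
      vc <- build_virtual_cell(polar)
    }
    log$rays_excl <- note("rd_profiles", rd_excluded,
                          "rays excluded (outside image)")
  }

  list(label_map = lm,
       in_map_raw = in_map_raw, in_map = in_map,
       average_profile = avg, features = features,
       virtual_cell = vc, log = dplyr::bind_rows(log))
}

#' Run the full multi-population pipeline
#'
#' For every population in the configuration: reads the two channels and
#' the selection file, segments nuclei, extracts and normalizes IN
#' profiles, denoises and compensates the profile map, computes the
#' average profile and per-profile features, reconstructs the virtual
#' cell from RD profiles, and persists every intermediate under
#' `config$out_dir`. Populations are then compared against the reference
#' with Mann-Whitney tests under Bonferroni correction and a report is
#' written.
#'
#' @param config A [run_config()] with at least one population.
#' @param rd Compute RD profiles / virtual cells (set `FALSE` to skip).
#' @return A `run_manifest` list: `config_hash`, `input_checksums`,
#'   `outputs`, `summary` (per-population tibble), `comparisons`
#'   (when >= 2 populations), `log`, `results` (in-memory per-population
#'   results), `manifest_path`.
#' @export
run_pipeline <- function(config, rd = TRUE) {
  stopifnot(inherits(config, "run_config"), length(config$populations) >= 1)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(config$seed, "pipeline"))

  results <- list(); outputs <- list(); checksums <- list()
  logs <- list()
  for (nm in names(config$populations)) {
    paths <- config$populations[[nm]]
    nuclear <- read_channel_tiff(paths$nuclear)
    protein <- read_channel_tiff(paths$protein)
    selections <- read_selection_csv(paths$selections)
    checksums[[nm]] <- as.list(tools::md5sum(
      unlist(paths[c("nuclear", "protein", "selections")])))

    res <- process_population(nuclear, protein, selections, config, rd = rd)
    results[[nm]] <- res
    pop_dir <- file.path(config$out_dir, nm)
    dir.create(pop_dir, recursive = TRUE, showWarnings = FALSE)
    out <- list()
    if (!is.null(res$in_map_raw)) {
      out$map_raw <- write_profile_map_csv(
        res$in_map_raw, file.path(pop_dir, "in_map_raw.csv"))
      out$map_compensated <- write_profile_map_csv(
        res$in_map, file.path(pop_dir, "in_map_compensated.csv"))
      out$average_profile <- file.path(pop_dir, "average_profile.csv")
      readr::write_csv(
        tibble::tibble(position = res$average_profile$position,
                       mean = res$average_profile$mean,
                       sd = res$average_profile$sd,
                       n = attr(res$average_profile, "n")),
        out$average_profile)
      out$features <- file.path(pop_dir, "features.csv")
      readr::write_csv(res$features, out$features)
      if (!is.null(res$in_map$warps)) {
        out$warps <- file.path(pop_dir, "warps.json")
        jsonlite::write_json(
          list(knots = res$in_map$warps$knots,
               displacements = res$in_map$warps$displacements),
          out$warps, digits = NA, matrix = "columnmajor")
      }
    }
    if (!is.null(res$virtual_cell)) {
      out$virtual_cell <- write_virtual_cell_png(
        res$virtual_cell, file.path(pop_dir, "virtual_cell.png"))
      out$virtual_cell_enhanced <- write_virtual_cell_png(
        enhance_contrast(res$virtual_cell, config$low_pct,
                         config$high_pct),
        file.path(pop_dir, "virtual_cell_enhanced.png"))
      out$polar <- file.path(pop_dir, "virtual_cell_polar.csv")
      readr::write_csv(as.data.frame(res$virtual_cell$polar), out$polar)
    }
    outputs[[nm]] <- out
    logs[[nm]] <- dplyr::mutate(res$log, population = nm, .before = 1)
  }

  summary <- purrr::map_dfr(names(results), function(nm) {
    if (is.null(results[[nm]]$features)) return(NULL)
    summarize_population(results[[nm]]$features, population = nm)
  })

  comparisons <- NULL
  with_features <- names(results)[
    !vapply(results, function(r) is.null(r$features), logical(1))]
  if (length(with_features) >= 2L &&
      config$reference %in% with_features) {
    comparisons <- compare_populations(
      lapply(results[with_features], `[[`, "features"),
      reference = config$reference, alpha = config$alpha,
      exact_max_n = config$exact_max_n)
    report_path <- file.path(config$out_dir, "report")
    write_report(summary, comparisons, report_path)
    outputs$report <- paste0(report_path, c(".csv", ".txt"))
  }

  log <- dplyr::bind_rows(logs)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    input_checksums = checksums,
    outputs = outputs,
    log = log,
    versions = list(profilecad = as.character(
      utils::packageVersion("profilecad")), r = R.version.string),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(
    manifest[c("config_hash", "seed", "input_checksums", "versions",
               "timestamp")],
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(log, file.path(config$out_dir, "run_log.csv"))

  structure(
    c(manifest, list(summary = summary, comparisons = comparisons,
                     results = results, manifest_path = manifest_path)),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat("  populations:", paste(names(x$results), collapse = ", "), "\n")
  if (!is.null(x$summary) && nrow(x$summary) > 0) {
    print(x$summary)
  }
  invisible(x)
}

#' Write the population report
#'
#' Emits a machine-readable CSV and a human-readable text table with one
#' row per population (number of IN profiles, membrane mean fluorescence
#' +/- SE, MMR +/- SE) followed by the pairwise comparisons and the
#' Bonferroni-corrected threshold.
#'
#' @param summary Population summary tibble.
#' @param comparisons A [compare_populations()] result (or NULL).
#' @param path Base path (without extension); writes `path.csv` and
#'   `path.txt`.
#' @return Base path, invisibly.
#' @export
write_report <- function(summary, comparisons, path) {
  readr::write_csv(summary, paste0(path, ".csv"))
  if (!is.null(comparisons)) {
    readr::write_csv(comparisons, paste0(path, "_comparisons.csv"))
  }
  txt <- c(
    "Population quantification",
    "",
    sprintf("%-14s %10s %26s %18s", "population", "n profiles",
            "membrane mean fluor. (+/-SE)", "MMR (+/-SE)"),
    vapply(seq_len(nrow(summary)), function(i) {
      s <- summary[i, ]
      sprintf("%-14s %10d %20.1f (+/-%.3f) %10.2f (+/-%.4f)",
              s$population, s$n_profiles,
              s$membrane_mean_mean, s$membrane_mean_se,
              s$mmr_mean, s$mmr_se)
    }, character(1))
  )
  if (!is.null(comparisons)) {
    txt <- c(txt, "",
             sprintf("Mann-Whitney vs %s, Bonferroni-corrected alpha = %.4g (%d tests)",
                     attr(comparisons, "reference"),
                     comparisons$alpha_corrected[1],
                     comparisons$n_comparisons[1]),
             vapply(seq_len(nrow(comparisons)), function(i) {
               cm <- comparisons[i, ]
               sprintf("  %-14s %-14s U=%9.1f  p=%.3g %s",
                       cm$population, cm$feature, cm$statistic, cm$p_raw,
                       if (cm$significant) "*" else "")
             }, character(1)))
  }
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
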