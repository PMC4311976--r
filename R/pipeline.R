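#' Default run configuration
#'
#' The defaults reproduce the measurement protocol constants: sections at
#' 25-65% length in 2.5% steps, 0.1 mm standardized pixels, 0.2 mm boundary
#' kernel, 12 training individuals per group, 12 stratified folds, 100
#' cross-validation repeats.
#'
#' @param ... named overrides.
#' @return configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = "phantom",            # "phantom" or a directory of TIFF volumes
    fractions = seq(25, 65, by = 2.5),
    pixel_mm = 0.1,
    bandwidth_mm = 0.2,
    voxel_mm = 0.3,
    scale_mode = "interspecific",
    per_group_train = 12L,
    n_folds = 12L,
    repeats = 100L,
    lambda_grid = NULL,
    properties = c("CBT", "SMA"),
    seed = 1L,
    out = NULL)
  utils::modifyList(cfg, list(...))
}

#' Read a configuration file (YAML key/value markup)
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return configuration list.
#' @export
read_config <- function(path, ...) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  utils::modifyList(cfg, list(...))
}

#' Position and measure one volume
#'
#' Applies the full positioning protocol (axis alignment, roll fixing,
#' mirroring of right-sided elements) and measures the 17 sections.
#'
#' @param vol a [bone_volume()] with landmarks (and `meta$side`).
#' @param config configuration list (see [default_config()]).
#' @return a `bone_profiles` object.
#' @export
measure_individual <- function(vol, config = default_config()) {
  r <- align_to_axis(vol)
  r <- fix_roll(r)
  r <- mirror_if_right(r)
  measure_rendering(r, fractions = config$fractions,
                    pixel_mm = config$pixel_mm,
                    bandwidth_mm = config$bandwidth_mm)
}

#' Run the full analysis pipeline
#'
#' Phantom-cohort generation (or volume loading), per-individual
#' measurement, morphometric map assembly, group summary statistics with
#' ANOVA and Student-Newman-Keuls comparisons, consensus/CV maps, and
#' penalized discriminant analysis with cross-validated penalty selection.
#' Deterministic given `config$seed`.  If `config$out` is set, CSV tables,
#' maps and a run log are written there.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @param cohort optional pre-generated cohort (list with `volumes` and
#'   `metadata`) to skip generation.
#' @return list with `metadata`, `profiles`, `maps` (per property),
#'   `consensus`, `cv`, `summaries`, `pda` (per property: split, selection,
#'   model, test classification), and `log`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  t0 <- Sys.time()
  log <- c(sprintf("cortmap %s | seed %d | %s",
                   as.character(utils::packageVersion("cortmap")),
                   config$seed, format(t0)),
           sprintf("config: %s", config_hash(config)))

  if (is.null(cohort)) {
    if (identical(config$input, "phantom")) {
      spec <- default_cohort_spec(seed = config$seed,
                                  voxel_mm = config$voxel_mm)
      cohort <- generate_cohort(spec)
    } else {
      cohort <- load_cohort_dir(config$input)
    }
  }
  meta <- cohort$metadata
  n <- nrow(meta)
  if (n == 0) stop("no input volumes")
  log <- c(log, sprintf("cohort: %d individuals (%s)", n,
                        paste(sprintf("%s:%d", names(table(meta$group)),
                                      table(meta$group)), collapse = ", ")))

  profiles <- vector("list", n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    profiles[[i]] <- tryCatch(
      measure_individual(cohort$volumes[[i]], config),
      error = function(e) {
        warning(sprintf("individual %s failed: %s", meta$id[i],
                        conditionMessage(e)))
        NULL
      })
    failed[i] <- is.null(profiles[[i]])
  }
  if (any(failed)) {
    log <- c(log, sprintf("skipped %d failed individuals: %s", sum(failed),
                          paste(meta$id[failed], collapse = ", ")))
    profiles <- profiles[!failed]
    meta <- meta[!failed, , drop = FALSE]
  }
  log <- c(log, sprintf("measured: %d sections x %d radii per individual",
                        length(config$fractions), 720L))

  std_mass <- standardization_mass(meta)
  maps <- list()
  for (prop in config$properties)
    maps[[prop]] <- lapply(seq_along(profiles), function(i)
      morphometric_map(profiles[[i]], prop, mass_kg = std_mass[i],
                       id = meta$id[i], group = meta$group[i]))

  groups <- sort(unique(meta$group))
  consensus <- cv <- list()
  for (prop in names(maps)) {
    consensus[[prop]] <- lapply(stats::setNames(groups, groups), function(g)
      consensus_map(maps[[prop]][meta$group == g]))
    cv[[prop]] <- lapply(stats::setNames(groups, groups), function(g)
      cv_map(maps[[prop]][meta$group == g]))
  }

  summaries <- list()
  for (prop in names(maps)) {
    raw <- lapply(profiles, `[[`, if (prop == "CBT") "thickness" else "sma")
    summaries[[prop]] <- lapply(stats::setNames(c(35, 50, 65),
                                                c("35%", "50%", "65%")),
                                function(fr)
                                  section_summary(raw, meta$group, fr,
                                                  fractions = config$fractions))
  }

  pda <- list()
  for (prop in names(maps)) {
    des <- map_design(maps[[prop]], meta$group)
    split <- split_train_test(des$labels,
                              per_group_train = config$per_group_train,
                              seed = config$seed)
    Omega <- penalty_matrix(des$grid[1], des$grid[2])
    sel <- select_lambda(des$X[split$train, , drop = FALSE],
                         des$labels[split$train], Omega = Omega,
                         grid = des$grid, lambda_grid = config$lambda_grid,
                         n_folds = config$n_folds, repeats = config$repeats,
                         seed = config$seed)
    model <- fit_pda(des$X[split$train, , drop = FALSE],
                     des$labels[split$train], lambda = sel$lambda,
                     Omega = Omega, grid = des$grid)
    test <- classify_pda(model, des$X[split$test, , drop = FALSE],
                         truth = des$labels[split$test])
    pda[[prop]] <- list(split = split, selection = sel, model = model,
                        test = test)
    log <- c(log, sprintf(
      "PDA %s: lambda %.4g, df %.2f, train misclass %d/%d, test misclass %d/%d",
      prop, sel$lambda, model$df, model$train_misclass, length(split$train),
      test$n_misclassified, length(split$test)))
  }

  log <- c(log, sprintf("elapsed %.1f s",
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  result <- list(metadata = meta, profiles = profiles, maps = maps,
                 consensus = consensus, cv = cv, summaries = summaries,
                 pda = pda, log = log)
  if (!is.null(config$out)) write_results(result, config)
  invisible(result)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "")
  # cheap stable checksum (sum of char codes), enough to tag a run log
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

load_cohort_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (length(files) == 0) stop(sprintf("no TIFF volumes found in '%s'", dir))
  vols <- lapply(files, read_volume_tiff)
  meta <- do.call(rbind, lapply(seq_along(vols), function(i) {
    m <- vols[[i]]$meta
    data.frame(id = m$id %||% basename(files[i]),
               group = m$group %||% "unknown",
               sex = m$sex %||% "U", side = m$side %||% "left",
               mass_kg = as.numeric(m$mass_kg %||% NA),
               length_mm = NA_real_, seed = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  list(volumes = vols, metadata = meta)
}

write_results <- function(result, config) {
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metadata, file.path(out, "metadata.csv"),
                   row.names = FALSE)
  for (prop in names(result$maps)) {
    d <- file.path(out, tolower(prop))
    dir.create(d, showWarnings = FALSE)
    for (i in seq_along(result$maps[[prop]]))
      export_map_csv(result$maps[[prop]][[i]],
                     file.path(d, sprintf("map_%s.csv",
                                          result$metadata$id[i])))
    anchors <- color_scale(result$consensus[[prop]], config$scale_mode)
    for (g in names(result$consensus[[prop]])) {
      export_map_csv(result$consensus[[prop]][[g]],
                     file.path(d, sprintf("consensus_%s.csv", g)))
      export_map_csv(result$cv[[prop]][[g]],
                     file.path(d, sprintf("cv_%s.csv", g)))
      if (requireNamespace("png", quietly = TRUE))
        export_map_png(render_map(result$consensus[[prop]][[g]],
                                  anchors[[g]]),
                       file.path(d, sprintf("consensus_%s.png", g)))
    }
    export_group_table(result$summaries[[prop]],
                       file.path(d, "group_table.csv"))
    save_pda_model(result$pda[[prop]]$model, file.path(d, "pda_model"))
    utils::write.csv(result$pda[[prop]]$selection$table,
                     file.path(d, "lambda_selection.csv"), row.names = FALSE)
  }
  writeLines(result$log, file.path(out, "run.log"))
  invisible(out)
}
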