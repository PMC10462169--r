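# End-to-end orchestration: select references -> simulate -> decode ->
# dedupe -> predict -> filter -> screen -> rank, with a run report that
# records the candidate count surviving each stage and the latent-profile
# feedback diagnostic.

#' Pipeline run configuration
#'
#' Either an in-memory synthetic fixture (`fixture_spec`) or file paths
#' (`dataset_path`, `latents_path`, `properties_path`) supply the data;
#' file inputs are turned into a codebook codec over the dataset itself.
#' One global `seed` derives independent per-stage streams (fixture draws,
#' generator noise, per-target predictor training), so identical configs
#' give identical reports.
#'
#' @param fixture_spec a [synthetic_spec()], or `NULL` when file paths are
#'   given.
#' @param dataset_path,latents_path,properties_path input CSV paths (see
#'   [read_dataset()], [read_latents()], [read_properties()]).
#' @param generator a [generator_config()].
#' @param predictor a [predictor_config()]; default
#'   [desk_predictor_config()] sized for codebook-scale data.
#' @param transporters transporter targets (default DAT, NET, SERT).
#' @param herg hERG target name (`NULL` to skip the safety axis).
#' @param novelty_max_sim novelty ceiling on cosine similarity to the
#'   references (default 0.5).
#' @param ranges screening range table (default [default_range_table()]).
#' @param out_dir optional directory for `leads.csv` and `report.json`.
#' @param seed global integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(fixture_spec = NULL, dataset_path = NULL,
                       latents_path = NULL, properties_path = NULL,
                       generator = generator_config(n_steps = 2000L,
                                                    burn_in = 100L,
                                                    snapshot_every = 10L),
                       predictor = desk_predictor_config(),
                       transporters = c("DAT", "NET", "SERT"),
                       herg = "hERG", novelty_max_sim = 0.5,
                       ranges = default_range_table(),
                       out_dir = NULL, seed = 1L) {
  from_files <- !is.null(dataset_path)
  if (is.null(fixture_spec) && !from_files) {
    stop_config("either fixture_spec or dataset_path must be given")
  }
  if (from_files) {
    for (p in c(dataset_path, latents_path, properties_path)) {
      if (!is.null(p) && !file.exists(p)) stop_config("missing input file: ", p)
    }
  }
  structure(list(fixture_spec = fixture_spec, dataset_path = dataset_path,
                 latents_path = latents_path,
                 properties_path = properties_path, generator = generator,
                 predictor = predictor, transporters = transporters,
                 herg = herg, novelty_max_sim = novelty_max_sim,
                 ranges = ranges, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain top-level keys `dataset`, `latents`, `properties`
#' (paths), `transporters`, `herg`, `novelty_max_sim`, `out_dir`, `seed`,
#' a `generator:` block with [generator_config()] fields, a `predictor:`
#' block with [predictor_config()] fields, and a `fixture:` block with
#' [synthetic_spec()] fields. Unknown keys are rejected. Relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("dataset", "latents", "properties", "transporters", "herg",
             "novelty_max_sim", "out_dir", "seed", "generator", "predictor",
             "fixture")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  rel <- function(p) {
    if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p
    else file.path(dirname(path), p)
  }
  gen <- do.call(generator_config,
                 utils::modifyList(list(n_steps = 2000L, burn_in = 100L,
                                        snapshot_every = 10L),
                                   raw$generator %||% list()))
  pred <- do.call(desk_predictor_config, raw$predictor %||% list())
  fixture <- if (!is.null(raw$fixture)) {
    do.call(synthetic_spec, raw$fixture)
  } else if (is.null(raw$dataset)) {
    synthetic_spec()
  }
  run_config(fixture_spec = fixture,
             dataset_path = rel(raw$dataset),
             latents_path = rel(raw$latents),
             properties_path = rel(raw$properties),
             generator = gen, predictor = pred,
             transporters = raw$transporters %||% c("DAT", "NET", "SERT"),
             herg = raw$herg %||% "hERG",
             novelty_max_sim = raw$novelty_max_sim %||% 0.5,
             out_dir = raw$out_dir, seed = raw$seed %||% 1L)
}

.log_stage <- function(verbose, ...) {
  if (verbose) message("[sgnc] ", ...)
}

#' Run the full lead-generation pipeline
#'
#' Executes the cascade: reference selection, Langevin simulation from the
#' seed latent vector, snapshot decoding and deduplication, per-target
#' affinity prediction and thresholding, novelty filtering against the
#' references, Lipinski filtering, property-range screening and
#' percent-excellent ranking. Surviving candidates are re-encoded and
#' their latent profile compared with the training set's
#' ([profile_divergence()]) as a decodability diagnostic.
#'
#' @param cfg a [run_config()].
#' @param verbose log stage progress to standard error (default FALSE).
#' @return an object of class `sgnc_run`: stage `counts`, the ranked
#'   `leads` table, `panel`, `verdicts`, `profile_divergence`, `refs`,
#'   `config` and `seed`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  targets <- c(cfg$transporters, cfg$herg)

  .log_stage(verbose, "loading inputs")
  if (!is.null(cfg$fixture_spec)) {
    spec <- cfg$fixture_spec
    spec$seed <- derive_seed(cfg$seed, "fixture")
    fx <- make_codebook_fixture(spec, transporters = cfg$transporters)
    molecules <- fx$molecules; latents <- fx$latents
    codec <- fx$codec; refs <- fx$refs; ref_table <- fx$ref_table
    seed_vector <- fx$seed_vector; profiles <- fx$profiles
  } else {
    molecules <- read_dataset(cfg$dataset_path)
    lat_df <- read_latents(cfg$latents_path)
    idx <- match(molecules$id, lat_df$id)
    if (anyNA(idx)) stop_data("latent vectors missing for some molecules")
    latents <- latent_matrix(lat_df)[idx, , drop = FALSE]
    codec <- codebook_codec(molecules, latents)
    ref_rows <- lapply(cfg$transporters, function(t) {
      sel <- select_references(molecules, latents, t)
      if (nrow(sel) == 0L) stop_data("no reference qualifies for '", t, "'")
      sel[1L, , drop = FALSE]
    })
    ref_table <- do.call(rbind, ref_rows)
    ref_lat <- latents[match(ref_table$id, molecules$id), , drop = FALSE]
    refs <- reference_set(ref_lat)
    seed_vector <- colMeans(ref_lat)
    profiles <- read_properties(cfg$properties_path)
  }

  .log_stage(verbose, "training ", length(targets), " affinity predictors")
  predictors <- lapply(stats::setNames(targets, targets), function(t) {
    rows <- molecules$target == t
    if (!any(rows)) stop_data("no training records for target '", t, "'")
    pc <- cfg$predictor
    pc$seed <- derive_seed(cfg$seed, paste0("predictor-", t))
    affinity_net(latents[rows, , drop = FALSE], molecules$delta_g[rows],
                 pc, target = t)
  })

  .log_stage(verbose, "simulating Langevin trajectory")
  gen <- cfg$generator
  gen$seed <- derive_seed(cfg$seed, "generator")
  traj <- simulate_langevin(seed_vector, refs, gen)
  candidates <- generate_candidates(traj, codec, gen)
  n_decoded <- length(snapshot_steps(gen))
  counts <- c(decoded = n_decoded, deduplicated = nrow(candidates))

  .log_stage(verbose, "predicting affinity panel for ", nrow(candidates),
             " candidates")
  panel <- predict_panel(candidates, predictors, targets)
  keep <- if (!is.null(cfg$herg)) {
    affinity_filter(panel, transporters = cfg$transporters, herg = cfg$herg)
  } else {
    pass <- rep(TRUE, nrow(panel))
    for (t in cfg$transporters) pass <- pass & panel[[t]] < -9.54
    pass
  }
  counts["affinity_pass"] <- sum(keep)

  novel <- novelty_filter(candidates, refs, max_sim = cfg$novelty_max_sim)
  keep <- keep & novel
  counts["novelty_pass"] <- sum(keep)

  desc <- molecules[match(candidates$id, molecules$id), , drop = FALSE]
  lip <- lipinski_filter(desc)$pass
  keep <- keep & lip
  counts["lipinski_pass"] <- sum(keep)

  .log_stage(verbose, "screening property profiles")
  prof_idx <- match(candidates$id, profiles$id)
  if (anyNA(prof_idx[keep])) {
    stop_data("property profiles missing for candidate(s): ",
              paste(head(candidates$id[keep & is.na(prof_idx)], 3L),
                    collapse = ", "))
  }
  verdicts <- screen_profiles(profiles[prof_idx[keep], , drop = FALSE],
                              cfg$ranges)
  screened_ids <- verdicts$id[verdicts$overall_pass]
  keep <- keep & candidates$id %in% screened_ids
  counts["screening_pass"] <- sum(keep)

  ranked <- rank_leads(verdicts)
  leads <- candidates[match(ranked$id, candidates$id), c("id", "smiles"),
                      drop = FALSE]
  leads <- cbind(leads, panel[match(ranked$id, panel$id), targets,
                              drop = FALSE])
  leads$pct_excellent <- ranked$pct_excellent
  rownames(leads) <- NULL

  div <- NA_real_
  if (nrow(leads) > 0L) {
    re_encoded <- encode(codec, leads$id)
    div <- profile_divergence(latent_profile(re_encoded),
                              latent_profile(latents))
  }

  report <- structure(
    list(counts = counts, leads = leads, panel = panel, verdicts = verdicts,
         ref_table = ref_table, refs = refs,
         profile_divergence = div, config = cfg, seed = cfg$seed),
    class = "sgnc_run")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_leads(file.path(cfg$out_dir, "leads.csv"), leads)
    jsonlite::write_json(
      list(seed = cfg$seed, counts = as.list(counts),
           n_leads = nrow(leads), leads = leads$id,
           profile_divergence = div),
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.sgnc_run <- function(x, ...) {
  cat("SGNC pipeline run (seed", x$seed, ")\n")
  cat("  stage counts:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("    %-14s %d\n", nm, x$counts[[nm]]))
  }
  cat("  ranked leads:", nrow(x$leads), "\n")
  if (nrow(x$leads) > 0L) {
    cat("  profile divergence of re-encoded leads:",
        signif(x$profile_divergence, 4), "\n")
  }
  invisible(x)
}

#' @export
summary.sgnc_run <- function(object, ...) {
  print(object)
  if (nrow(object$leads) > 0L) {
    cat("\nTop leads:\n")
    print(utils::head(object$leads, 5L), row.names = FALSE)
  }
  invisible(object)
}
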