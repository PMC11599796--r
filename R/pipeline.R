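# Pipeline driver: chains simulate -> rank -> features -> states ->
# cross-assay from a single YAML configuration, writing CSV outputs and a
# JSON run manifest with input/output digests so deterministic stages can
# be verified and resumed.

pipeline_defaults <- function() {
  list(k_factor = 20, scale = 400, baseline = 1000,
       sg_window = 25, sg_polyorder = 3,
       step = 3, k = 8, umap_seed = 42, seed = 1)
}

apply_defaults <- function(cfg) {
  def <- pipeline_defaults()
  for (nm in names(def)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- def[[nm]]
      message("config: using default ", nm, " = ", def[[nm]])
    }
  }
  cfg
}

digest_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the dominance-analysis pipeline from a configuration file
#'
#' Executes the requested stages in dependency order:
#' `simulate_matches` -> `ranking` (Elo, David, DCI, stability per assay)
#' -> `cross_assay` (score correlations, stable-pair reversals) and
#' `simulate_pose` -> `features` -> `states` (clustering, distributions,
#' enrichment). Every default the configuration does not set is logged.
#' All outputs are CSV under `out_dir`, and a JSON manifest records the
#' configuration snapshot, seeds, package version, per-stage outputs and
#' their digests. When a manifest from a previous run with an identical
#' configuration exists, stages whose outputs are present with matching
#' digests are skipped.
#'
#' @param config path to a YAML file, or an equivalent named list. Keys:
#'   `out_dir` (required), `seed`, stage blocks `simulate_matches`,
#'   `ranking`, `cross_assay`, `simulate_pose`, `features`, `states`, and
#'   scalar defaults (`k_factor`, `scale`, `baseline`, `sg_window`,
#'   `sg_polyorder`, `step`, `k`, `umap_seed`).
#' @return The run manifest (named list, invisibly also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop_validation("config must be a YAML file or a list")
  if (is.null(cfg$out_dir)) stop_validation("config field missing: out_dir")
  cfg <- apply_defaults(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, paste0(...))

  cfg_digest <- digest_string(cfg)
  prev <- NULL
  manifest_path <- path("manifest.json")
  if (file.exists(manifest_path)) {
    prev <- tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
    if (!is.null(prev) && !identical(prev$config_digest, cfg_digest)) prev <- NULL
  }
  manifest <- list(version = as.character(packageVersion("domsuite")),
                   config = cfg, config_digest = cfg_digest,
                   seed = cfg$seed, stages = list())

  stage_current <- function(name, outputs) {
    if (is.null(prev)) return(FALSE)
    st <- prev$stages[[name]]
    if (is.null(st) || is.null(st$digests)) return(FALSE)
    if (!all(file.exists(outputs))) return(FALSE)
    identical(lapply(digest_files(outputs), unname),
              lapply(st$digests, function(d) d))
  }
  record <- function(name, outputs, status = "ok") {
    manifest$stages[[name]] <<- list(status = status, outputs = as.list(outputs),
                                     digests = digest_files(outputs))
  }
  fail <- function(name, err) {
    manifest$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(err))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  # --- simulate_matches ------------------------------------------------
  if (!is.null(cfg$simulate_matches)) {
    sm <- cfg$simulate_matches
    outs <- c(path("matches.csv"), path("truth.csv"))
    if (stage_current("simulate_matches", outs)) {
      message("stage simulate_matches: up to date, skipped")
      record("simulate_matches", outs, "skipped")
    } else {
      tryCatch({
        assays <- unlist(sm$assays %||% list(tube = FALSE))
        hc <- hierarchy_config(
          n_animals = sm$n_animals %||% 4,
          beta = sm$beta %||% 3, tie_prob = sm$tie_prob %||% 0.1,
          trials_per_dyad = sm$trials_per_dyad %||% 6,
          assays = assays, cage = sm$cage %||% "cage1",
          seed = sm$seed %||% cfg$seed)
        gen <- generate_matches(hc)
        write_matches(gen$matches, outs[1])
        write.csv(gen$truth, outs[2], row.names = FALSE, quote = FALSE)
        record("simulate_matches", outs)
      }, error = function(e) fail("simulate_matches", e))
    }
  }

  # --- ranking ---------------------------------------------------------
  if (!is.null(cfg$ranking)) {
    matches_path <- cfg$ranking$matches %||% path("matches.csv")
    outs <- c(path("scores.csv"), path("dci.csv"), path("stability.csv"))
    if (stage_current("ranking", outs)) {
      message("stage ranking: up to date, skipped")
      record("ranking", outs, "skipped")
    } else {
      tryCatch({
        matches <- read_matches(matches_path)
        ecfg <- elo_config(cfg$k_factor, cfg$scale, cfg$baseline)
        groups <- split(seq_len(nrow(matches)),
                        paste(matches$assay, matches$cage, sep = "\r"))
        scores <- do.call(rbind, lapply(groups, function(idx) {
          m <- matches[idx, , drop = FALSE]
          class(m) <- c("match_records", "data.frame")
          elo <- elo_ratings(m, cfg = ecfg)
          ds <- tryCatch(david_scores(m)$ds[names(elo$final)],
                         error = function(e) rep(NA_real_, length(elo$final)))
          data.frame(assay = m$assay[1], cage = m$cage[1],
                     animal = names(elo$final), elo = unname(elo$final),
                     elo_rank = unname(elo$rank), david = unname(ds),
                     stringsAsFactors = FALSE)
        }))
        rownames(scores) <- NULL
        write.csv(scores, outs[1], row.names = FALSE, quote = FALSE)
        dcis <- do.call(rbind, lapply(groups, function(idx) {
          m <- matches[idx, , drop = FALSE]
          val <- tryCatch(dci(m), error = function(e) NA_real_)
          data.frame(assay = m$assay[1], cage = m$cage[1], dci = val)
        }))
        rownames(dcis) <- NULL
        write.csv(dcis, outs[2], row.names = FALSE, quote = FALSE)
        stab <- dyad_stability_table(matches)
        write.csv(as.data.frame(stab), outs[3], row.names = FALSE, quote = FALSE)
        record("ranking", outs)
      }, error = function(e) fail("ranking", e))
    }
  }

  # --- cross_assay -----------------------------------------------------
  if (isTRUE(cfg$cross_assay) || is.list(cfg$cross_assay)) {
    outs <- c(path("correlations.csv"), path("reversals.csv"))
    if (stage_current("cross_assay", outs)) {
      message("stage cross_assay: up to date, skipped")
      record("cross_assay", outs, "skipped")
    } else {
      tryCatch({
        scores <- read.csv(path("scores.csv"), stringsAsFactors = FALSE)
        panel <- score_panel(data.frame(animal = scores$animal,
                                        assay = scores$assay,
                                        score = scores$elo))
        cm <- score_correlation_matrix(panel)
        long <- as.data.frame(as.table(cm$r), stringsAsFactors = FALSE)
        names(long) <- c("assay_1", "assay_2", "r")
        long$p <- as.vector(cm$p)
        long$n <- as.vector(cm$n)
        write.csv(long, outs[1], row.names = FALSE, quote = FALSE)
        stab <- read.csv(path("stability.csv"), stringsAsFactors = FALSE)
        assays <- unique(stab$assay)
        revs <- list()
        if (length(assays) > 1) {
          for (i in seq_along(assays)) for (j in seq_along(assays)) {
            if (j <= i) next
            revs[[length(revs) + 1]] <- rank_reversals(
              stab[stab$assay == assays[i], ], stab[stab$assay == assays[j], ])
          }
        }
        revs <- if (length(revs)) do.call(rbind, revs) else
          data.frame(assay_1 = character(), assay_2 = character(),
                     stable_both = integer(), maintained = integer(),
                     reversed = integer(), excluded = integer())
        write.csv(revs, outs[2], row.names = FALSE, quote = FALSE)
        record("cross_assay", outs)
      }, error = function(e) fail("cross_assay", e))
    }
  }

  # --- simulate_pose ---------------------------------------------------
  if (!is.null(cfg$simulate_pose)) {
    sp <- cfg$simulate_pose
    n_rec <- sp$n_recordings %||% 2
    rec_ids <- sprintf("rec%02d", seq_len(n_rec))
    outs <- c(path("pose_", rec_ids, ".csv"), path("pose_ranks.csv"))
    if (stage_current("simulate_pose", outs)) {
      message("stage simulate_pose: up to date, skipped")
      record("simulate_pose", outs, "skipped")
    } else {
      tryCatch({
        # cycle recordings over the 6 dyads of a 4-animal cage so every
        # rank difference 1..3 is represented
        dyads <- t(combn(1:4, 2))
        ranks <- data.frame(recording = rec_ids,
                            rank_a = dyads[(seq_len(n_rec) - 1) %% 6 + 1, 1],
                            rank_b = dyads[(seq_len(n_rec) - 1) %% 6 + 1, 2])
        mult3 <- sp$avert_dwell_multiplier_rank3 %||% 1
        for (i in seq_len(n_rec)) {
          rd <- abs(ranks$rank_a[i] - ranks$rank_b[i])
          pc <- pose_sim_config(
            frames = sp$frames %||% 1500, fps = sp$fps %||% 30,
            noise_sd = sp$noise_sd %||% 2,
            missing_frac = sp$missing_frac %||% 0.05,
            avert_dwell_multiplier = if (rd == 3) mult3 else 1,
            seed = (sp$seed %||% cfg$seed) + i, id = rec_ids[i])
          write_pose_csv(generate_pose(pc), outs[i])
        }
        write.csv(ranks, outs[n_rec + 1], row.names = FALSE, quote = FALSE)
        record("simulate_pose", outs)
      }, error = function(e) fail("simulate_pose", e))
    }
  }

  # --- features --------------------------------------------------------
  if (!is.null(cfg$features) && !isFALSE(cfg$features)) {
    pose_files <- Sys.glob(path("pose_rec*.csv"))
    outs <- path("features.csv")
    if (stage_current("features", outs)) {
      message("stage features: up to date, skipped")
      record("features", outs, "skipped")
    } else {
      tryCatch({
        if (length(pose_files) == 0) stop_validation("no pose recordings found")
        feats <- lapply(pose_files, function(f) {
          rec <- read_pose_csv(f)
          rec <- interpolate_and_smooth(rec, window = cfg$sg_window,
                                        polyorder = cfg$sg_polyorder)
          compute_features(rec)
        })
        names(feats) <- sub("^pose_", "", sub("[.]csv$", "", basename(pose_files)))
        fm <- pool_zscore_subsample(feats, step = cfg$step)
        out_df <- cbind(fm$provenance, as.data.frame(fm$x))
        write.csv(out_df, outs, row.names = FALSE, quote = FALSE)
        record("features", outs)
      }, error = function(e) fail("features", e))
    }
  }

  # --- states ----------------------------------------------------------
  if (!is.null(cfg$states) && !isFALSE(cfg$states)) {
    st <- if (is.list(cfg$states)) cfg$states else list()
    outs <- c(path("assignments.csv"), path("distribution.csv"),
              path("enrichment.csv"), path("model.json"), path("embedding.csv"))
    if (stage_current("states", outs)) {
      message("stage states: up to date, skipped")
      record("states", outs, "skipped")
    } else {
      tryCatch({
        fdf <- read.csv(path("features.csv"), stringsAsFactors = FALSE)
        fm <- structure(list(x = as.matrix(fdf[, FEATURE_NAMES]),
                             provenance = fdf[, c("recording", "frame")],
                             step = cfg$step),
                        class = "feature_matrix")
        model <- fit_states(fm, k = st$k %||% cfg$k,
                            seed = st$seed %||% cfg$seed)
        ranks_path <- path("pose_ranks.csv")
        ranks <- if (file.exists(ranks_path)) {
          read.csv(ranks_path, stringsAsFactors = FALSE)
        } else NULL
        assign <- state_assignment(model, ranks = ranks)
        write.csv(as.data.frame(assign), outs[1], row.names = FALSE, quote = FALSE)
        dist <- cluster_distribution(assign)
        write.csv(data.frame(recording = rownames(dist), dist,
                             check.names = FALSE),
                  outs[2], row.names = FALSE, quote = FALSE)
        if (!is.null(ranks)) {
          enr <- percent_enriched(assign)
          write.csv(data.frame(rank_diff = rownames(enr$enrichment),
                               enr$enrichment, check.names = FALSE),
                    outs[3], row.names = FALSE, quote = FALSE)
        } else {
          write.csv(data.frame(), outs[3], row.names = FALSE)
        }
        jsonlite::write_json(list(k = model$k, seed = model$seed,
                                  inertia = model$inertia,
                                  centroids = model$centroids),
                             outs[4], auto_unbox = TRUE, digits = NA)
        emb <- embed_2d(fm, seed = st$umap_seed %||% cfg$umap_seed)
        write.csv(cbind(fm$provenance, emb), outs[5],
                  row.names = FALSE, quote = FALSE)
        record("states", outs)
      }, error = function(e) fail("states", e))
    }
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Stable digest of a configuration list.
digest_string <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}
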