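# Synthetic generators with known ground truth. Match streams come from a
# Bradley-Terry-style latent hierarchy; arena trajectories come from a
# Markov dwell model over scripted two-mouse states with a rigid skeleton
# template, pixel noise and missing-at-random node dropout.

#' Latent-hierarchy configuration for match generation
#'
#' @param n_animals animals per cage (default 4).
#' @param latent latent dominance scores, one per animal; must be distinct.
#'   Default `n_animals..1` (animal 1 highest).
#' @param beta steepness of the hierarchy: the probability that i beats j
#'   in a decisive trial is `plogis(beta * (d_i - d_j))` (default 3, a
#'   steep, near-deterministic hierarchy on unit-spaced scores).
#' @param tie_prob probability that any trial ties (default 0.1).
#' @param trials_per_dyad decisive-or-tied trials per dyad per assay
#'   (default 6).
#' @param assays named logical vector: which assays to generate and whether
#'   each is inverted (an inverted assay flips every decisive outcome,
#'   mimicking a paradigm that rewards the opposite of the latent order).
#' @param cage cage identifier.
#' @param seed RNG seed.
#' @return A list of class `hierarchy_config`.
#' @export
hierarchy_config <- function(n_animals = 4, latent = NULL, beta = 3,
                             tie_prob = 0.1, trials_per_dyad = 6,
                             assays = c(agonistic = FALSE, urine = FALSE,
                                        tube = FALSE, reward = FALSE),
                             cage = "cage1", seed = 1) {
  latent <- latent %||% rev(seq_len(n_animals))
  if (length(latent) != n_animals) stop_validation("latent must have n_animals scores")
  if (anyDuplicated(latent)) stop_validation("latent scores must be distinct")
  if (tie_prob < 0 || tie_prob >= 1) stop_validation("tie_prob must be in [0, 1)")
  if (beta < 0) stop_validation("beta must be non-negative")
  if (!all(names(assays) %in% ASSAYS)) {
    stop_validation("assay names must be among: ", paste(ASSAYS, collapse = ", "))
  }
  structure(list(n_animals = n_animals, latent = latent, beta = beta,
                 tie_prob = tie_prob, trials_per_dyad = trials_per_dyad,
                 assays = assays, cage = cage, seed = seed),
            class = "hierarchy_config")
}

#' Generate dyadic match streams from a latent hierarchy
#'
#' For each assay, dyad and trial: the trial ties with `tie_prob`;
#' otherwise animal i beats j with probability
#' `plogis(beta * (d_i - d_j))`, with the direction flipped for inverted
#' assays. Matches receive chronological order indices by round-robin over
#' dyads. Output is identical for a fixed seed.
#'
#' @param cfg a [hierarchy_config()].
#' @return A list with `matches` (a `match_records` data frame) and
#'   `truth` (data frame `animal, latent, true_rank`).
#' @export
generate_matches <- function(cfg) {
  stopifnot(inherits(cfg, "hierarchy_config"))
  ids <- sprintf("m%02d", seq_len(cfg$n_animals))
  dyads <- t(combn(seq_len(cfg$n_animals), 2))
  with_seed(cfg$seed, {
    per_assay <- lapply(names(cfg$assays), function(assay) {
      inverted <- cfg$assays[[assay]]
      # round-robin over dyads within each trial block
      i <- rep(dyads[, 1], times = cfg$trials_per_dyad)
      j <- rep(dyads[, 2], times = cfg$trials_per_dyad)
      n <- length(i)
      tie <- runif(n) < cfg$tie_prob
      p_i <- stats::plogis(cfg$beta * (cfg$latent[i] - cfg$latent[j]))
      i_wins <- runif(n) < p_i
      if (inverted) i_wins <- !i_wins
      outcome <- ifelse(tie, "TIE", ifelse(i_wins, "A_WINS", "B_WINS"))
      data.frame(assay = assay, cage = cfg$cage, order = seq_len(n),
                 id_a = ids[i], id_b = ids[j], outcome = outcome,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_assay)
    matches <- match_records(df$assay, df$cage, df$order, df$id_a, df$id_b,
                             df$outcome)
    truth <- data.frame(animal = ids, latent = cfg$latent,
                        true_rank = simplify_ranks(setNames(cfg$latent, ids)),
                        stringsAsFactors = FALSE)
    list(matches = matches, truth = truth)
  })
}

POSE_STATES <- c("BOTH_AT_PORT", "PORT_AND_NEAR_AVERT",
                 "PORT_AND_BACKWALL", "ROAMING")

#' Configuration for the two-mouse arena trajectory generator
#'
#' @param frames number of frames (default 3000, ~100 s at 30 fps).
#' @param fps frames per second (default 30).
#' @param arena `c(width, height)` pixels (default 640 x 480).
#' @param port port landmark; default mid-top wall `c(arena[1]/2, 5)`.
#' @param states subset of `"BOTH_AT_PORT"`, `"PORT_AND_NEAR_AVERT"`,
#'   `"PORT_AND_BACKWALL"`, `"ROAMING"` to script.
#' @param mean_dwell mean dwell per state in frames (default 240, i.e. 8 s
#'   at 30 fps: reward-competition states track multi-second trial epochs
#'   such as a 10 s reward tone, and dwells must comfortably exceed the
#'   cross-arena travel time for per-frame state labels to be meaningful).
#' @param avert_dwell_multiplier multiplier on the `PORT_AND_NEAR_AVERT`
#'   dwell, used to inflate that state for large-rank-gap dyads
#'   (default 1).
#' @param noise_sd Gaussian pixel noise added to every node (default 2).
#' @param missing_frac fraction of node-frames masked missing-at-random
#'   (default 0.05).
#' @param seed RNG seed.
#' @param id recording identifier.
#' @return A list of class `pose_sim_config`.
#' @export
pose_sim_config <- function(frames = 3000, fps = 30, arena = c(640, 480),
                            port = NULL,
                            states = c("BOTH_AT_PORT", "PORT_AND_NEAR_AVERT",
                                       "PORT_AND_BACKWALL"),
                            mean_dwell = 240, avert_dwell_multiplier = 1,
                            noise_sd = 2, missing_frac = 0.05,
                            seed = 1, id = "sim") {
  if (!all(states %in% POSE_STATES)) {
    stop_validation("unknown state(s): ",
                    paste(setdiff(states, POSE_STATES), collapse = ", "))
  }
  if (missing_frac < 0 || missing_frac >= 1) {
    stop_validation("missing_frac must be in [0, 1)")
  }
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  port <- port %||% c(arena[1] / 2, 5)
  structure(list(frames = frames, fps = fps, arena = arena, port = port,
                 states = states, mean_dwell = mean_dwell,
                 avert_dwell_multiplier = avert_dwell_multiplier,
                 noise_sd = noise_sd, missing_frac = missing_frac,
                 seed = seed, id = id),
            class = "pose_sim_config")
}

# Rigid skeleton template rotated to a heading: nose 25 px ahead of the
# thorax, forehead 15 px, ears +/- 8 px lateral of the forehead, tail base
# 30 px behind. Features use only nose/thorax/port geometry, so the
# template needs no biomechanical realism.
skeleton_at <- function(thorax, heading) {
  u <- c(cos(heading), sin(heading))
  perp <- c(-u[2], u[1])
  rbind(nose = thorax + 25 * u,
        forehead = thorax + 15 * u,
        left_ear = thorax + 15 * u + 8 * perp,
        right_ear = thorax + 15 * u - 8 * perp,
        thorax = thorax,
        tail_base = thorax - 30 * u)
}

# Anchor thorax positions and heading rules for both animals in a scripted
# state. Headings are rules ("toward" / "away" from the port, or a fixed
# random angle) evaluated at the animal's current position every frame, so
# an animal facing the port keeps facing it while it jostles around.
state_geometry <- function(state, port, arena) {
  jit <- function(s = 3) runif(2, -s, s)
  if (state == "BOTH_AT_PORT") {
    # both noses close to the port, facing it
    list(t1 = port + c(-20, 25) + jit(), h1 = "toward",
         t2 = port + c(20, 25) + jit(), h2 = "toward")
  } else if (state == "PORT_AND_NEAR_AVERT") {
    # animal 1 at the port; animal 2 in the port half of the arena (clearly
    # off the back wall) but facing away from the port
    list(t1 = port + c(0, 28) + jit(), h1 = "toward",
         t2 = port + c(90, 200) + jit(), h2 = "away")
  } else if (state == "PORT_AND_BACKWALL") {
    # animal 1 at the port; animal 2 along the far wall facing away
    list(t1 = port + c(0, 28) + jit(), h1 = "toward",
         t2 = c(runif(1, arena[1] * 0.25, arena[1] * 0.75),
                arena[2] - 10) + jit(2), h2 = "away")
  } else { # ROAMING
    list(t1 = c(runif(1, 40, arena[1] - 40), runif(1, 40, arena[2] - 40)),
         h1 = runif(1, -pi, pi),
         t2 = c(runif(1, 40, arena[1] - 40), runif(1, 40, arena[2] - 40)),
         h2 = runif(1, -pi, pi))
  }
}

heading_at <- function(rule, pos, port) {
  if (is.numeric(rule)) return(rule)
  ang <- atan2(port[2] - pos[2], port[1] - pos[1])
  if (rule == "away") ang + pi else ang
}

#' Generate a scripted two-mouse pose recording
#'
#' Simulates a Markov state sequence (geometric dwell with the configured
#' mean; transitions uniform over the other states), places both animals'
#' 6-node skeletons according to the state script, adds Gaussian pixel
#' noise to every node, and masks a missing-at-random fraction of
#' node-frames. Per-frame true state labels and the port landmark are
#' carried in the result. Output is bit-identical for a fixed seed.
#'
#' @param cfg a [pose_sim_config()].
#' @return A `pose_recording` with `state_truth` set.
#' @export
generate_pose <- function(cfg) {
  stopifnot(inherits(cfg, "pose_sim_config"))
  states <- cfg$states
  n <- cfg$frames
  with_seed(cfg$seed, {
    dwell <- setNames(rep(cfg$mean_dwell, length(states)), states)
    if ("PORT_AND_NEAR_AVERT" %in% states) {
      dwell[["PORT_AND_NEAR_AVERT"]] <-
        dwell[["PORT_AND_NEAR_AVERT"]] * cfg$avert_dwell_multiplier
    }
    seq_states <- character(n)
    coords <- array(NA_real_, c(2, length(POSE_NODES), n, 2))
    cur <- sample(states, 1)
    # Animals move continuously. Each dwell episode has an anchor geometry;
    # animals are pulled toward their anchor (entering a state is a
    # speed-capped walk, not a teleport) while sustaining correlated
    # locomotor wander around it, so thorax velocity has the continuous,
    # non-degenerate distribution real tracked mice show rather than a
    # zero-versus-sprint dichotomy.
    vmax <- 5    # px/frame locomotion cap (~10 cm/s): unhurried arena ambling
    wander_sd <- 2.2  # per-axis innovation of the velocity process
    g <- state_geometry(cur, cfg$port, cfg$arena)
    pos1 <- g$t1; pos2 <- g$t2
    vel1 <- c(0, 0); vel2 <- c(0, 0)
    advance <- function(pos, vel, anchor) {
      move <- 0.85 * vel + rnorm(2, 0, wander_sd) + 0.12 * (anchor - pos)
      speed <- sqrt(sum(move^2))
      if (speed > vmax) move <- move / speed * vmax
      list(pos = pos + move, vel = move)
    }
    f <- 1L
    while (f <= n) {
      len <- 1L + stats::rgeom(1, 1 / max(dwell[[cur]], 1))
      upto <- min(n, f + len - 1L)
      seq_states[f:upto] <- cur
      g <- state_geometry(cur, cfg$port, cfg$arena)
      for (fr in f:upto) {
        s1 <- advance(pos1, vel1, g$t1); pos1 <- s1$pos; vel1 <- s1$vel
        s2 <- advance(pos2, vel2, g$t2); pos2 <- s2$pos; vel2 <- s2$vel
        h1 <- heading_at(g$h1, pos1, cfg$port) + runif(1, -0.05, 0.05)
        h2 <- heading_at(g$h2, pos2, cfg$port) + runif(1, -0.05, 0.05)
        coords[1, , fr, ] <- skeleton_at(pos1, h1)
        coords[2, , fr, ] <- skeleton_at(pos2, h2)
      }
      f <- upto + 1L
      if (length(states) > 1) cur <- sample(setdiff(states, cur), 1)
    }
    if (cfg$noise_sd > 0) {
      coords <- coords + rnorm(length(coords), 0, cfg$noise_sd)
    }
    if (cfg$missing_frac > 0) {
      # drop whole (animal, node, frame) detections: x and y go together
      mask <- array(runif(2 * length(POSE_NODES) * n) < cfg$missing_frac,
                    c(2, length(POSE_NODES), n))
      for (ax in 1:2) coords[, , , ax][mask] <- NA_real_
    }
    pose_recording(coords, port = cfg$port, fps = cfg$fps,
                   state_truth = seq_states, id = cfg$id)
  })
}
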