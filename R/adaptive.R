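#' Configuration of a FAST adaptive-sampling campaign
#'
#' @param generations number of swarm generations (default 16).
#' @param swarm_size simulations per generation (default 20).
#' @param segment_length length of each segment, ns (default 50).
#' @param extension_length final per-seed extension target, ns (default 100).
#' @param k_gen clusters per generation over the accumulated data (default
#'   100, capped at the available frame count at run time).
#' @param alpha directed-vs-undirected balance in [0, 1]: 1 ranks purely by
#'   reward, 0 purely by (inverse) visit counts.
#' @param seed integer campaign seed (required).
#' @return object of class `campaign_config`.
#' @export
campaign_config <- function(generations = 16L, swarm_size = 20L,
                            segment_length = 50, extension_length = 100,
                            k_gen = 100L, alpha = 1, seed) {
  for (v in c(generations, swarm_size, k_gen)) stopifnot_count(v, "campaign counts")
  if (segment_length <= 0 || extension_length < segment_length) {
    stop("campaign_config: need 0 < segment_length <= extension_length")
  }
  if (alpha < 0 || alpha > 1) stop("campaign_config: alpha must be in [0, 1]")
  if (missing(seed)) stop("campaign_config: seed is required")
  structure(list(generations = as.integer(generations),
                 swarm_size = as.integer(swarm_size),
                 segment_length = segment_length,
                 extension_length = extension_length,
                 k_gen = as.integer(k_gen), alpha = alpha,
                 seed = as.integer(seed)),
            class = "campaign_config")
}

#' Campaign bookkeeping without simulation
#'
#' Plan-only accounting of a campaign: segment count and total simulated
#' time after all segments are extended to `extension_length`.
#'
#' @param config a [campaign_config()].
#' @return list: `n_segments`, `total_time_ns`, `total_time_us`,
#'   `per_generation` data.frame.
#' @export
campaign_plan <- function(config) {
  n_seg <- config$generations * config$swarm_size
  total_ns <- n_seg * config$extension_length
  per_gen <- data.frame(generation = seq_len(config$generations),
                        segments = config$swarm_size,
                        segment_length_ns = config$segment_length,
                        extended_length_ns = config$extension_length)
  list(n_segments = n_seg, total_time_ns = total_ns,
       total_time_us = total_ns / 1e3, per_generation = per_gen)
}

#' Rank clusters and draw seed frames
#'
#' Score = alpha * normalised(mean reward) + (1 - alpha) * normalised
#' (1 / (1 + visits)); the top `n_seeds` clusters are selected (ties to the
#' lower cluster index) and one member frame is drawn uniformly (seeded)
#' from each. Empty clusters among the top ranks are skipped and the next
#' rank is taken.
#'
#' @param visit_counts per-cluster frame counts.
#' @param rewards per-cluster mean reward (NA allowed for empty clusters).
#' @param members list: per-cluster frame indices into the accumulated data.
#' @param alpha balance in [0, 1].
#' @param n_seeds number of seeds to select.
#' @param seed RNG seed (required).
#' @return list: `clusters` (chosen cluster indices in rank order),
#'   `frames` (one accumulated-frame index per chosen cluster).
#' @export
rank_and_seed <- function(visit_counts, rewards, members, alpha, n_seeds,
                          seed) {
  k <- length(visit_counts)
  if (n_seeds > k) stop("rank_and_seed: n_seeds exceeds cluster count")
  norm01 <- function(x) {
    x[!is.finite(x)] <- min(x[is.finite(x)], 0)
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  score <- alpha * norm01(rewards) + (1 - alpha) * norm01(1 / (1 + visit_counts))
  ord <- order(-score, seq_len(k))     # ties: lower cluster index first
  rng <- local_rng(seed)
  chosen <- integer(0)
  frames <- integer(0)
  for (c_id in ord) {
    if (length(chosen) >= n_seeds) break
    mem <- members[[c_id]]
    if (length(mem) == 0L) next        # empty cluster: take the next rank
    chosen <- c(chosen, c_id)
    pick <- if (length(mem) == 1L) mem else mem[rng$sample_int(length(mem), 1L)]
    frames <- c(frames, pick)
  }
  if (length(chosen) < n_seeds) stop("rank_and_seed: not enough non-empty clusters")
  list(clusters = chosen, frames = frames)
}

#' Run a FAST adaptive-sampling campaign
#'
#' Generation 0 starts every swarm member from `start`, with distinct seeds
#' derived from the campaign seed. Each later generation pools all
#' accumulated frames, clusters them into `k_gen` microstates (k-means on
#' the frame features), computes per-cluster mean rewards and visit counts,
#' and restarts the swarm from frames chosen by [rank_and_seed()]. After the
#' final generation every segment is extended from `segment_length` to
#' `extension_length`. The per-generation maximum (and mean) reward trace is
#' recorded.
#'
#' @param simulator callable `(start, n_steps, seed)` returning a
#'   (steps + 1) x d matrix of states; must be deterministic under `seed`.
#' @param featurizer callable mapping a state matrix to per-frame reward
#'   values (numeric vector).
#' @param config a [campaign_config()]; `segment_length` and
#'   `extension_length` are in simulator steps here when `steps_per_ns = 1`.
#' @param start initial state (vector).
#' @param steps_per_ns conversion from ns to simulator steps (default 1).
#' @return object of class `campaign_state`: accumulated `trajectories`
#'   (list of matrices), `reward_trace` (data.frame generation, max_reward,
#'   mean_reward, max_reward_cum — the non-decreasing best-so-far),
#'   `chosen_seeds` per generation, `total_simulated_time_ns`, `n_segments`.
#' @export
run_campaign <- function(simulator, featurizer, config, start,
                         steps_per_ns = 1) {
  seg_steps <- max(1L, round(config$segment_length * steps_per_ns))
  ext_steps <- max(1L, round(config$extension_length * steps_per_ns))
  trajs <- list()
  seg_meta <- list()
  trace <- data.frame(generation = integer(0), max_reward = numeric(0),
                      mean_reward = numeric(0))
  chosen_log <- list()
  seed_counter <- config$seed
  next_seed <- function() {
    seed_counter <<- seed_counter + 1L
    seed_counter
  }
  starts <- replicate(config$swarm_size, start, simplify = FALSE)
  for (gen in seq_len(config$generations)) {
    for (s in seq_len(config$swarm_size)) {
      sd_i <- next_seed()
      out <- simulator(starts[[s]], seg_steps, sd_i)
      if (is.null(out) || any(!is.finite(out))) {
        stop(sprintf("run_campaign: simulator failure at generation %d segment %d", gen, s))
      }
      trajs[[length(trajs) + 1L]] <- out
      seg_meta[[length(seg_meta) + 1L]] <- list(generation = gen, seed = sd_i)
    }
    rewards_all <- lapply(trajs, featurizer)
    gen_rewards <- unlist(rewards_all[(length(trajs) - config$swarm_size + 1L):length(trajs)])
    trace <- rbind(trace, data.frame(generation = gen,
                                     max_reward = max(gen_rewards),
                                     mean_reward = mean(gen_rewards)))
    if (gen == config$generations) break
    # cluster all accumulated frames on their full state features
    Xall <- do.call(rbind, trajs)
    r_all <- unlist(rewards_all)
    k_use <- min(config$k_gen, nrow(Xall))
    km <- kmeans_cluster(Xall, k_use, seed = next_seed())
    assign_all <- unlist(km$dtrajs)
    visits <- tabulate(assign_all, nbins = k_use)
    mean_rew <- vapply(seq_len(k_use), function(c_id) {
      v <- r_all[assign_all == c_id]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    members <- split(seq_along(assign_all), factor(assign_all, levels = seq_len(k_use)))
    sel <- rank_and_seed(visits, mean_rew, members, config$alpha,
                         config$swarm_size, seed = next_seed())
    chosen_log[[gen]] <- sel
    starts <- lapply(sel$frames, function(fi) Xall[fi, ])
  }
  # extend every segment to the extension length
  extra <- ext_steps - seg_steps
  if (extra > 0L) {
    for (i in seq_along(trajs)) {
      last <- trajs[[i]][nrow(trajs[[i]]), ]
      out <- simulator(last, extra, next_seed())
      trajs[[i]] <- rbind(trajs[[i]], out[-1L, , drop = FALSE])
    }
  }
  trace$max_reward_cum <- cummax(trace$max_reward)
  n_segments <- length(trajs)
  total_ns <- n_segments * config$extension_length
  structure(list(trajectories = trajs, reward_trace = trace,
                 chosen_seeds = chosen_log,
                 n_segments = n_segments,
                 total_simulated_time_ns = total_ns,
                 config = config),
            class = "campaign_state")
}
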