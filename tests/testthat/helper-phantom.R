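# Small phantoms shared across tests. The full 6 mm / 61 x 61 / 10 us
# acquisition geometry is exercised where a check is about the default
# conditions; everything replicate-heavy runs on these reduced grids.

small_grid <- function(extent = 1, window = 4e-6, start = 14e-6) {
  scan_grid(extent_x = extent, extent_y = extent, step = 0.1,
            window_duration = window, window_start_time = start)
}

tiny_grid <- function() small_grid(extent = 0.6, window = 3e-6)

small_phantom <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(grid = small_grid(), explant_radius = 0.5, seed = seed)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

tiny_phantom <- function(seed = 1, ...) {
  small_phantom(seed = seed, grid = tiny_grid(), explant_radius = 0.3, ...)
}

# envelope -> peaks -> qus for one volume
run_pipeline <- function(vol, floor = 0.05) {
  env <- compute_envelope(vol)
  peaks <- detect_volume_peaks(env, floor = floor)
  list(env = env, peaks = peaks, qus = compute_qus(env, peaks))
}

# Brute-force per-line two-peak selection: plain loops, same rule as
# detect_line_peaks (local maxima above floor after the ring-down guard,
# amplitude NMS within the half merge window, candidate-mean scoring over
# every representative pair).
oracle_two_peaks <- function(env_line, grid, floor = 0.05,
                             merge_window = 1e-6, guard = 1e-7) {
  n <- length(env_line)
  guard_n <- ceiling(guard * grid$sampling_rate)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (i <= guard_n || env_line[i] < floor) next
    if (env_line[i - 1] == env_line[i]) next   # not the first of a plateau
    l <- i - 1
    r <- i + 1
    while (r <= n && env_line[r] == env_line[i]) r <- r + 1
    if (r > n) next
    if (env_line[l] < env_line[i] && env_line[r] < env_line[i]) {
      cand <- c(cand, i)
    }
  }
  if (length(cand) < 2L) return(NULL)
  t_cand <- grid$window_start_time + (cand - 1) / grid$sampling_rate
  a_cand <- env_line[cand]
  half <- merge_window / 2
  # NMS by amplitude, ties to earlier time
  ord <- order(-a_cand, t_cand)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) if (abs(t_cand[k] - t_cand[i]) <= half) ok <- FALSE
    if (ok) kept <- c(kept, i)
  }
  kept <- sort(kept)
  if (length(kept) < 2L) return(NULL)
  score <- numeric(length(kept))
  for (m in seq_along(kept)) {
    s <- 0
    cnt <- 0
    for (j in seq_along(cand)) {
      if (abs(t_cand[j] - t_cand[kept[m]]) <= half) {
        s <- s + a_cand[j]
        cnt <- cnt + 1
      }
    }
    score[m] <- s / cnt
  }
  # exhaustive pair search over representatives: maximize the score sum,
  # ties toward the earlier pair
  best <- NULL; best_key <- c(-Inf, Inf, Inf)
  for (p in seq_along(kept)) {
    for (q in seq_along(kept)) {
      if (q <= p) next
      key <- c(score[p] + score[q], t_cand[kept[p]], t_cand[kept[q]])
      better <- key[1] > best_key[1] + 1e-15 ||
        (abs(key[1] - best_key[1]) <= 1e-15 &&
           (key[2] < best_key[2] ||
              (key[2] == best_key[2] && key[3] < best_key[3])))
      if (better) { best <- c(kept[p], kept[q]); best_key <- key }
    }
  }
  list(ac_time = t_cand[best[1]], cbi_time = t_cand[best[2]])
}
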