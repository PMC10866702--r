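# Independent oracles and fixture builders shared across the suite.

# Brute-force 1-D mass transport: move supply left-to-right onto demand,
# accumulating |i - j| ground distance. For 1-D distributions this greedy
# plan is optimal, and it shares no code with the cumulative-sum formula.
oracle_emd_1d <- function(p, q) {
  n <- length(p)
  supply <- p
  demand <- q
  cost <- 0
  i <- 1L
  j <- 1L
  while (i <= n && j <= n) {
    if (supply[i] <= 1e-15) {
      i <- i + 1L
    } else if (demand[j] <= 1e-15) {
      j <- j + 1L
    } else {
      m <- min(supply[i], demand[j])
      cost <- cost + m * abs(i - j)
      supply[i] <- supply[i] - m
      demand[j] <- demand[j] - m
    }
  }
  cost / (n - 1L)
}

oracle_emd_similarity <- function(h1, h2) {
  d <- oracle_emd_1d(h1$gaap, h2$gaap) + oracle_emd_1d(h1$accdv, h2$accdv) +
    oracle_emd_1d(h1$gyrdv, h2$gyrdv) + oracle_emd_1d(h1$totba, h2$totba)
  -(d / 4)^2
}

random_hist_set <- function() {
  r <- function(n) {
    x <- stats::rexp(n)
    x / sum(x)
  }
  hist_set(r(11), r(11), r(6), r(2))
}

point_hist_set <- function(gaap_bin, accdv_bin = 6L, gyrdv_bin = 3L,
                           moving = FALSE) {
  one_hot <- function(n, i) {
    v <- numeric(n)
    v[i] <- 1
    v
  }
  hist_set(one_hot(11, gaap_bin), one_hot(11, accdv_bin),
           one_hot(6, gyrdv_bin), if (moving) c(0, 1) else c(1, 0))
}

# naive windowed-count oracle for the moving mean
oracle_moving_mean <- function(counts, w) {
  n <- length(counts)
  if (n < w) return(numeric(0))
  vapply(w:n, function(i) mean(counts[(i - w + 1L):i]), numeric(1))
}

# feature_series fixture with constant per-segment values (no filtering; the
# series is built directly on the 300 ms grid at 200 Hz)
constant_feature_series <- function(gaap, accdv = 0, gyrdv = 0, totba = 0) {
  n_seg <- length(gaap)
  spp <- 60L
  expand <- function(x) rep(rep_len(x, n_seg), each = spp)
  structure(list(gaap = expand(gaap), accdv = expand(accdv),
                 gyrdv = expand(gyrdv), totba = expand(totba),
                 time = (seq_len(n_seg * spp) - 1L) / 200,
                 sample_rate = 200, warmup_s = 0),
            class = "feature_series")
}

# three tight synthetic clusters with known membership
three_cluster_fixture <- function(seed = 42, per = 10L) {
  protos <- list(action_prototype(1, -40, -120, 0),
                 action_prototype(2, 0, 0, 1),
                 action_prototype(3, 40, 120, 0.5))
  jitter_hist <- function(h, eps = 0.02) {
    hist_set(h$gaap + stats::runif(11, 0, eps),
             h$accdv + stats::runif(11, 0, eps),
             h$gyrdv + stats::runif(6, 0, eps),
             h$totba + stats::runif(2, 0, eps), normalize = TRUE)
  }
  withr::with_seed(seed, {
    hists <- unlist(lapply(protos, function(p) {
      replicate(per, jitter_hist(p$hist), simplify = FALSE)
    }), recursive = FALSE)
    list(hists = hists, truth = rep(1:3, each = per), protos = protos)
  })
}

# structured synthetic predictor table: labels drawn from a multinomial
# logit with known coefficients (reference class "decreasing")
simulate_table <- function(n, b_sim = c(2, -1), b_time = c(-1.5, 0.5),
                           seed = 1) {
  withr::with_seed(seed, {
    sim <- stats::rnorm(n)
    tt <- stats::rnorm(n)
    lin_s <- b_sim[1] * sim + b_time[1] * tt       # sustained_increase
    lin_t <- b_sim[2] * sim + b_time[2] * tt       # transient
    den <- 1 + exp(lin_s) + exp(lin_t)
    p <- cbind(1 / den, exp(lin_s) / den, exp(lin_t) / den)
    lab <- apply(p, 1, function(pr) {
      sample(c("decreasing", "sustained_increase", "transient"), 1, prob = pr)
    })
    predictor_table(sim, tt, lab)
  })
}
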