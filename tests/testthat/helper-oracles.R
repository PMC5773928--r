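# Independent oracle implementations used to cross-check the package.
# These are deliberately written as plain, slow loops, sharing no code with
# the implementations they validate.

# numerical integration of the single-sine daily degree-day model
oracle_sine_dd <- function(tmin, tmax, base, n_points = 10000L) {
  m <- (tmin + tmax) / 2
  a <- (tmax - tmin) / 2
  t <- (seq_len(n_points) - 0.5) / n_points
  temp <- m + a * sin(2 * pi * t)
  mean(pmax(temp - base, 0))
}

# straightforward re-implementation of hourly resampling + gap fill
oracle_fill <- function(raw, large_gap_hours = 3) {
  t_obs <- as.numeric(raw$timestamp)
  grid <- seq(ceiling(t_obs[1] / 3600) * 3600,
              floor(t_obs[length(t_obs)] / 3600) * 3600, by = 3600)
  val <- rep(NA_real_, length(grid))
  flag <- rep(NA_character_, length(grid))
  for (g in seq_along(grid)) {
    tg <- grid[g]
    hit <- which(t_obs == tg)
    if (length(hit)) {
      val[g] <- raw$temp_c[hit[1]]
      flag[g] <- "observed"
      next
    }
    before <- max(which(t_obs < tg))
    after <- min(which(t_obs > tg))
    if ((t_obs[after] - t_obs[before]) / 3600 <= large_gap_hours) {
      w <- (tg - t_obs[before]) / (t_obs[after] - t_obs[before])
      val[g] <- raw$temp_c[before] * (1 - w) + raw$temp_c[after] * w
      flag[g] <- "interpolated_small_gap"
    }
  }
  # day-over-day pass for the remaining hours
  for (g in which(is.na(val))) {
    hod <- grid[g] %% 86400
    same <- which(!is.na(val) & grid %% 86400 == hod)
    before <- same[same < g]
    after <- same[same > g]
    if (!length(before) || !length(after)) stop("oracle: unfillable")
    b <- max(before); a <- min(after)
    w <- (grid[g] - grid[b]) / (grid[a] - grid[b])
    val[g] <- val[b] * (1 - w) + val[a] * w
    flag[g] <- "interpolated_day_over_day"
  }
  tibble::tibble(timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
                 temp_c = val, fill_flag = flag)
}

# brute-force day-of-year groupby for normals
oracle_normals <- function(dates, values) {
  key <- format(dates, "%m-%d")
  out <- NULL
  pop_sd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
  for (k in sort(unique(key))) {
    v <- values[key == k]
    out <- rbind(out, data.frame(
      month = as.integer(substr(k, 1, 2)), day = as.integer(substr(k, 4, 5)),
      n = length(v), mean = mean(v), min = min(v), max = max(v),
      std = pop_sd(v),
      q25 = unname(quantile(v, 0.25)), median = unname(quantile(v, 0.5)),
      q75 = unname(quantile(v, 0.75))
    ))
  }
  out
}

# closed-form simple OLS via the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_reg <- sum((yhat - mean(y))^2)
  f <- ss_reg / (ss_res / (n - 2))
  list(slope = slope, intercept = intercept, F = f,
       p = pf(f, 1, n - 2, lower.tail = FALSE))
}

# count-based (cohort) re-implementation of the elimination simulation under
# constant temperature; distributionally identical to the agent model because
# deaths are exchangeable Bernoulli draws and same-day eggs share development
oracle_cohort_sim <- function(p, temp_c, max_days = 1000) {
  nf <- max(1, round(p[["n_initial_females"]]))
  dd_day <- sapply(c("egg", "larva", "pupa", "immature_adult"), function(s) {
    max(temp_c - p[[paste0("base_", s)]], 0)
  })
  dd_req <- sapply(c("egg", "larva", "pupa", "immature_adult"), function(s) {
    p[[paste0("dd_", s)]]
  })
  mu <- sapply(c("egg", "larva", "pupa", "immature_adult", "mature_adult"),
               function(s) p[[paste0("mu_", s)]])
  ctrl <- p[["control_mortality_daily"]]
  # cohorts: stage (1..4 juvenile, 5 mature), dev, count, plus sex/mated splits
  # for adults; mature adults split into males and female mating classes
  juv <- data.frame(stage = integer(), dev = numeric(), count = integer(),
                    sexed = logical(), f = integer(), m = integer())
  fem <- c(unmated = nf, fertile = 0, sterile = 0)
  males <- nf
  for (d in seq_len(max_days)) {
    # development (constant temp: whole-day increments; juveniles may advance)
    if (nrow(juv)) {
      for (i in seq_len(nrow(juv))) {
        s <- juv$stage[i]
        gain <- dd_day[s]
        juv$dev[i] <- juv$dev[i] + gain
        while (s <= 4 && juv$dev[i] >= dd_req[s]) {
          juv$dev[i] <- juv$dev[i] - dd_req[s]
          s <- s + 1
          juv$stage[i] <- s
          if (s == 4 && !juv$sexed[i]) {
            juv$f[i] <- rbinom(1, juv$count[i], 0.5)
            juv$m[i] <- juv$count[i] - juv$f[i]
            juv$sexed[i] <- TRUE
          }
        }
      }
      mature <- juv$stage > 4
      if (any(mature)) {
        fem[["unmated"]] <- fem[["unmated"]] + sum(juv$f[mature])
        males <- males + sum(juv$m[mature])
        juv <- juv[!mature, , drop = FALSE]
      }
    }
    # no acute deaths at warm constant temperature
    # daily mortality
    surv <- function(n, s) if (n > 0) rbinom(1, n, (1 - mu[s]) * (1 - ctrl)) else 0L
    if (nrow(juv)) {
      for (i in seq_len(nrow(juv))) {
        s <- min(juv$stage[i], 4)
        if (juv$sexed[i]) {
          juv$f[i] <- surv(juv$f[i], s)
          juv$m[i] <- surv(juv$m[i], s)
          juv$count[i] <- juv$f[i] + juv$m[i]
        } else {
          juv$count[i] <- surv(juv$count[i], s)
        }
      }
      juv <- juv[juv$count > 0, , drop = FALSE]
    }
    fem <- sapply(fem, surv, s = 5)
    names(fem) <- c("unmated", "fertile", "sterile")
    males <- surv(males, 5)
    # mating
    if (fem[["unmated"]] > 0) {
      ster <- rbinom(1, fem[["unmated"]], p[["p_sit_daily"]])
      rest <- fem[["unmated"]] - ster
      fem[["sterile"]] <- fem[["sterile"]] + ster
      if (males > 0) {
        fem[["fertile"]] <- fem[["fertile"]] + rest
        fem[["unmated"]] <- 0
      } else {
        fem[["unmated"]] <- rest
      }
    }
    # oviposition
    scale <- max(temp_c - p[["base_egg"]], 0) / (25 - p[["base_egg"]])
    lam <- p[["fecundity"]] * scale
    if (fem[["fertile"]] > 0 && lam > 0) {
      eggs <- rpois(1, fem[["fertile"]] * lam)
      if (eggs > 0) {
        juv <- rbind(juv, data.frame(stage = 1L, dev = 0, count = eggs,
                                     sexed = FALSE, f = 0L, m = 0L))
      }
    }
    total <- sum(juv$count) + sum(fem) + males
    if (total == 0) return(d)
  }
  NA_integer_
}

# expected elimination day when reproduction is impossible: the maximum of
# n iid geometric(q) lifetimes, E[T] = sum_d P(T > d)
oracle_pure_death_mean <- function(n_agents, q, max_days = 10000) {
  d <- 0:max_days
  sum(1 - (1 - (1 - q)^d)^n_agents)
}
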