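# Independent oracles the implementation is checked against. These are
# deliberately brute-force and share no code with the package internals.

# two-point-line interpolation: for each NA gap, draw the straight line
# between the last valid sample before and first valid after; edges hold
oracle_interpolate <- function(time_ms, pupil) {
  out <- pupil
  n <- length(pupil)
  valid <- which(!is.na(pupil))
  for (i in which(is.na(pupil))) {
    before <- valid[valid < i]
    after <- valid[valid > i]
    if (length(before) == 0) {
      out[i] <- pupil[after[1]]
    } else if (length(after) == 0) {
      out[i] <- pupil[before[length(before)]]
    } else {
      i0 <- before[length(before)]
      i1 <- after[1]
      w <- (time_ms[i] - time_ms[i0]) / (time_ms[i1] - time_ms[i0])
      out[i] <- pupil[i0] + w * (pupil[i1] - pupil[i0])
    }
  }
  out
}

# interval union on a boolean 1 ms timeline: mark each span widened by the
# margin, clip, and read maximal runs back off the timeline
oracle_extend_margins <- function(spans, margin_ms, block_range) {
  lo <- block_range[1]
  hi <- block_range[2]
  timeline <- rep(FALSE, hi - lo)
  for (i in seq_len(nrow(spans))) {
    a <- max(spans$start_ms[i] - margin_ms, lo)
    b <- min(spans$end_ms[i] + margin_ms, hi)
    if (b > a) timeline[(a - lo + 1):(b - lo)] <- TRUE
  }
  r <- rle(timeline)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(
    start_ms = lo + starts[r$values] - 1,
    end_ms = lo + ends[r$values]
  )
}

# closed-form Holm step-down adjustment
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# prediction-grid EMM oracle: build the full factor grid, predict each cell
# from the fixed effects, average with equal weights over non-focal factors
oracle_emm <- function(model, focal) {
  fit <- model$fit
  df <- model$data
  fixed <- model$fixed
  grid <- expand.grid(lapply(fixed, function(f) levels(df[[f]])),
                      stringsAsFactors = FALSE)
  names(grid) <- fixed
  for (f in fixed) {
    grid[[f]] <- factor(grid[[f]], levels = levels(df[[f]]))
    contrasts(grid[[f]]) <- contrasts(df[[f]])
  }
  rhs <- paste(fixed, collapse = if (model$interactions) " * " else " + ")
  X <- model.matrix(as.formula(paste("~", rhs)), grid)
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  key <- interaction(grid[focal], drop = FALSE, lex.order = FALSE)
  L <- t(sapply(levels(key), function(k) colMeans(X[key == k, , drop = FALSE])))
  est <- as.numeric(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  lev <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
  out <- as.data.frame(lev, stringsAsFactors = FALSE)
  names(out) <- focal
  out$estimate <- est
  out$se <- se
  out
}

# ordinary least squares rmse from the normal equations
oracle_ols_rmse <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sqrt(mean((y - X %*% beta)^2))
}
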