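# Desk-scale baseline predictors. A "model" is a factory object with a
# `fit(train, estop)` function returning a prediction function
# `function(newdata) numeric`. All models consume standardized record
# data.frames (descriptor columns + connectivity_key + logS + optional
# weight) so the evaluation machinery can swap them freely; they stand in
# for the GPU-scale learners the evaluation protocol was designed around.

descriptor_columns <- function() {
  c("n_heavy_atoms", "n_aromatic_rings", "hbd", "hba", "heteroatom_fraction")
}

model_design <- function(records) {
  require_columns(records, descriptor_columns(), "records")
  as.matrix(cbind(1, records[, descriptor_columns()]))
}

record_weights <- function(records) {
  if (is.null(records$weight)) rep(1, nrow(records)) else records$weight
}

#' Weighted-mean baseline predictor
#'
#' Predicts the weighted mean of the training values for every query; the
#' floor every informative model must beat.
#'
#' @return A model factory (list with `name` and `fit`).
#' @export
model_mean <- function() {
  structure(list(
    name = "mean",
    fit = function(train, estop = NULL) {
      data <- rbind(train, estop)
      w <- record_weights(data)
      m <- sum(w * data$logS) / sum(w)
      function(newdata) rep(unname(m), nrow(newdata))
    }), class = "sol_model")
}

#' Ridge-regression baseline predictor
#'
#' Weighted linear least squares on the five-descriptor vector with an L2
#' penalty chosen on the early-stopping subset only (the internal 9%
#' split); the training subset never sees the penalty choice. Supports
#' record weights so weighted (curated) training is testable. A degenerate
#' design falls back to the intercept-only model.
#'
#' @param lambda_grid Candidate penalties, evaluated on the early-stop
#'   subset; the grid includes 0 so noiseless data can be fit exactly.
#' @return A model factory (list with `name` and `fit`).
#' @export
model_ridge <- function(lambda_grid = c(0, 10^seq(-4, 2, length.out = 13))) {
  force(lambda_grid)
  structure(list(
    name = "ridge",
    fit = function(train, estop = NULL) {
      if (nrow(train) < 2L) stop("ridge needs at least 2 training records")
      X <- model_design(train)
      y <- train$logS
      w <- record_weights(train)
      p <- ncol(X)
      pen <- diag(p); pen[1L, 1L] <- 0          # intercept unpenalized
      xtwx <- crossprod(X, w * X)
      xtwy <- crossprod(X, w * y)
      coef_for <- function(lambda) {
        b <- try(solve(xtwx + lambda * pen, xtwy), silent = TRUE)
        if (inherits(b, "try-error")) NULL else b
      }
      if (!is.null(estop) && nrow(estop) > 0L) {
        Xe <- model_design(estop)
        err <- vapply(lambda_grid, function(l) {
          b <- coef_for(l)
          if (is.null(b)) return(Inf)
          sqrt(mean((drop(Xe %*% b) - estop$logS)^2))
        }, numeric(1))
        lambda <- lambda_grid[which.min(err)]
      } else lambda <- min(lambda_grid)
      beta <- coef_for(lambda)
      if (is.null(beta)) {                      # degenerate design
        m <- sum(w * y) / sum(w)
        return(function(newdata) rep(unname(m), nrow(newdata)))
      }
      function(newdata) unname(drop(model_design(newdata) %*% beta))
    }), class = "sol_model")
}

#' Memorizing predictor (duplicate-leakage probe)
#'
#' Predicts the training value for an exact connectivity-key match and the
#' weighted training mean otherwise. It exists purely to demonstrate the
#' error deflation caused by duplicated molecules straddling a by-record
#' split; it has no generalization ability at all.
#'
#' @return A model factory (list with `name` and `fit`).
#' @export
model_memorizer <- function() {
  structure(list(
    name = "memorizer",
    fit = function(train, estop = NULL) {
      data <- rbind(train, estop)
      require_columns(data, "connectivity_key", "train")
      w <- record_weights(data)
      fallback <- sum(w * data$logS) / sum(w)
      lut <- tapply(data$logS, data$connectivity_key, mean)
      function(newdata) {
        hit <- as.vector(lut[newdata$connectivity_key])
        unname(ifelse(is.na(hit), fallback, hit))
      }
    }), class = "sol_model")
}

#' Oracle predictor knowing the synthetic ground truth
#'
#' Returns the generator's true logS for every molecule it knows; its
#' cross-validated RMSE therefore estimates the irreducible measurement
#' noise of the generated data, which makes it the reference point for
#' noise-recovery checks.
#'
#' @param truth Ground-truth table from [ground_truth()].
#' @return A model factory (list with `name` and `fit`).
#' @export
model_oracle <- function(truth) {
  require_columns(truth, c("connectivity_key", "true_logS"), "truth")
  lut <- tapply(truth$true_logS, truth$connectivity_key, mean)
  fallback <- mean(truth$true_logS)
  structure(list(
    name = "oracle",
    fit = function(train, estop = NULL) {
      function(newdata) {
        hit <- as.vector(lut[newdata$connectivity_key])
        unname(ifelse(is.na(hit), fallback, hit))
      }
    }), class = "sol_model")
}

#' @export
print.sol_model <- function(x, ...) {
  cat("solcurate model factory:", x$name, "\n")
  invisible(x)
}
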