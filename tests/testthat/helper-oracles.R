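# Independent oracles used across the suite.

# Horn quaternion-method superposition RMSD (independent of the SVD/Kabsch
# implementation under test)
quaternion_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  M <- crossprod(a0, b0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[1, 3] + M[3, 1]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(a0^2) + sum(b0^2) - 2 * lam) / nrow(a))
}

# brute-force centred moving average truncated at the termini
brute_moving_average <- function(x, window) {
  half <- (window - 1) / 2
  vapply(seq_along(x), function(i)
    mean(x[max(1, i - half):min(length(x), i + half)]), numeric(1))
}

# brute-force column-identity tally for repeat perfection
brute_repeat_perfection <- function(full, L) {
  res <- strsplit(full, "")[[1]]
  cols <- split(res, ((seq_along(res) - 1) %% L) + 1)
  mean(vapply(cols, function(ch) max(table(ch)) / length(ch), numeric(1)))
}

# random rigid transform applied to a structure model
random_rigid <- function(model, seed) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  repeatfold:::transform_model(model, Rz %*% Ry %*% Rx,
                               stats::runif(3, -20, 20))
}

# designed clean solenoid sequence: hydrophobic core, polar surface
clean_unit <- function(L, seed) {
  set.seed(seed)
  core <- c("V", "I", "L", "F"); surf <- c("S", "T", "N", "Q", "G")
  u <- character(L)
  even <- (seq_len(L) - 1) %% 2 == 0
  u[even] <- sample(core, sum(even), replace = TRUE)
  u[!even] <- sample(surf, sum(!even), replace = TRUE)
  paste(u, collapse = "")
}
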