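# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive-path log-likelihood of a Gaussian-emission HMM (sum over all
# K^T hidden paths); NA observations contribute likelihood 1.
enum_loglik <- function(obs, means, sds, trans, init) {
  K <- length(means)
  T_ <- length(obs)
  emis <- function(x, k) if (is.na(x)) 1 else dnorm(x, means[k], sds[k])
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- init[paths[r, 1]] * emis(obs[1], paths[r, 1])
    if (T_ > 1) {
      for (t in 2:T_) {
        p <- p * trans[paths[r, t - 1], paths[r, t]] * emis(obs[t], paths[r, t])
      }
    }
    total <- total + p
  }
  log(total)
}

# Exhaustive most-probable path; ties broken toward the lexicographically
# smallest path (matching lowest-state-index tie-breaking).
enum_viterbi <- function(obs, means, sds, trans, init) {
  K <- length(means)
  T_ <- length(obs)
  emis <- function(x, k) if (is.na(x)) 1 else dnorm(x, means[k], sds[k])
  grid <- expand.grid(rep(list(seq_len(K)), T_))
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  paths <- as.matrix(grid)
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    lp <- log(init[paths[r, 1]]) + log(emis(obs[1], paths[r, 1]))
    if (T_ > 1) {
      for (t in 2:T_) {
        lp <- lp + log(trans[paths[r, t - 1], paths[r, t]]) +
          log(emis(obs[t], paths[r, t]))
      }
    }
    if (lp > best + 1e-12) {
      best <- lp
      best_path <- paths[r, ]
    }
  }
  list(path = unname(best_path), logprob = best)
}

random_hmm <- function(K = 3) {
  means <- sort(runif(K, 0.1, 0.9), decreasing = TRUE)
  sds <- runif(K, 0.03, 0.1)
  trans <- matrix(rgamma(K * K, 1) + 0.05, K, K)
  trans <- trans / rowSums(trans)
  init <- rgamma(K, 1) + 0.05
  init <- init / sum(init)
  list(means = means, sds = sds, transition = trans, init = init)
}

# All-pairs halogen-pi scan using an independent plane fit (prcomp).
brute_halogen_pi <- function(atoms, ligand_name, max_distance = 4.5,
                             max_face_angle = 40) {
  lig <- atoms[atoms$residue_name == ligand_name, ]
  hal <- lig[lig$element %in% c("CL", "BR", "I", "F"), ]
  bases <- atoms[toupper(atoms$residue_name) %in%
                   c("A", "G", "C", "U", "T") &
                   atoms$residue_name != ligand_name, ]
  keys <- unique(bases[, c("chain", "resno", "residue_name")])
  out <- NULL
  for (r in seq_len(nrow(keys))) {
    res <- bases[bases$chain == keys$chain[r] & bases$resno == keys$resno[r], ]
    ringn <- if (toupper(keys$residue_name[r]) %in% c("A", "G")) {
      c("N1", "C2", "N3", "C4", "C5", "C6")
    } else c("N1", "C2", "N3", "C4", "C5", "C6")
    sel <- res[match(ringn, res$atom_name), ]
    if (anyNA(sel$atom_name)) next
    xyz <- as.matrix(sel[, c("x", "y", "z")])
    centroid <- colMeans(xyz)
    pc <- prcomp(xyz, center = TRUE)
    normal <- pc$rotation[, 3]
    for (h in seq_len(nrow(hal))) {
      v <- as.numeric(hal[h, c("x", "y", "z")]) - centroid
      d <- sqrt(sum(v^2))
      if (d > max_distance) next
      ang <- acos(min(1, abs(sum(v * normal)) / d)) * 180 / pi
      out <- rbind(out, data.frame(
        halogen_atom = hal$atom_name[h], ring_resno = keys$resno[r],
        distance = d, angle = ang, face_on = ang <= max_face_angle
      ))
    }
  }
  if (is.null(out)) return(out)
  out[order(out$distance), ]
}

# All-pairs polar-contact scan with explicit loops.
brute_polar <- function(atoms, ligand_name, max_distance = 3.6) {
  lig <- atoms[atoms$residue_name == ligand_name, ]
  donors <- lig[lig$element %in% c("CL", "BR", "I", "F", "O"), ]
  partners <- atoms[atoms$element %in% c("N", "O") &
                      atoms$residue_name != ligand_name, ]
  out <- NULL
  for (i in seq_len(nrow(donors))) {
    for (j in seq_len(nrow(partners))) {
      d <- sqrt(sum((as.numeric(donors[i, c("x", "y", "z")]) -
                       as.numeric(partners[j, c("x", "y", "z")]))^2))
      if (d <= max_distance) {
        out <- rbind(out, data.frame(
          ligand_atom = donors$atom_name[i],
          partner_atom = partners$atom_name[j],
          partner_resno = partners$resno[j], distance = d
        ))
      }
    }
  }
  if (is.null(out)) return(out)
  out[order(out$distance), ]
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

rotate_atoms <- function(atoms, rot, shift = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# Two-fluorophore staircase trace (total 1600 -> 800 -> 0 plus noise).
two_step_trace <- function(b1, b2, n = 400, noise = 40) {
  total <- c(rep(1600, b1 - 1), rep(800, b2 - b1), rep(0, n - b2 + 1))
  tibble::tibble(
    donor = total / 2 + rnorm(n, 0, noise),
    acceptor = total / 2 + rnorm(n, 0, noise)
  )
}
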