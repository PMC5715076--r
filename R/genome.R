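#' @title Genome and growth-policy networks
#' @description A tree's growth strategy is encoded by 34 genes in
#'   `[0, 1]`: 3 branching-angle genes, 18 weights of the primary-growth
#'   network (2 inputs, 3 hidden tanh neurons, 3 outputs), 10 weights of
#'   the secondary-growth network (2 inputs, 3 hidden neurons, 1 output)
#'   and 3 neutral marker genes used only for visualisation. Both networks
#'   carry one extra bias neuron in the hidden layer that emits a constant
#'   unit signal.
#' @name genome-networks
NULL

GENOME_LENGTH <- 34L

#' Draw a uniform random genome
#' @param n number of genomes.
#' @return A numeric vector (or `n x 34` matrix for `n > 1`) of genes in
#'   `[0, 1]`.
#' @export
random_genome <- function(n = 1) {
  g <- matrix(runif(n * GENOME_LENGTH), n, GENOME_LENGTH)
  if (n == 1) drop(g) else g
}

#' Decode a genome
#'
#' Genes map affinely to network weights, `w = 2 g - 1`, and to the
#' branching angles: `theta1` in `[0, 90]` degrees, `theta2` in
#' `[-90, 0]` degrees and `gamma` in `[0, 180]` degrees, so that the two
#' children of a node fork on opposite sides of the parent axis.
#'
#' @param genome numeric vector of 34 genes in `[0, 1]`.
#' @return A list with `angles` (theta1, theta2, gamma in degrees),
#'   `primary` and `secondary` networks (each `list(I, O)`), and
#'   `markers`.
#' @export
decode_genome <- function(genome) {
  if (length(genome) != GENOME_LENGTH)
    stop("genome must have ", GENOME_LENGTH, " genes")
  if (any(genome < 0 | genome > 1)) stop("genes must lie in [0, 1]")
  w <- 2 * genome - 1
  angles <- c(theta1 = 90 * genome[1], theta2 = -90 * genome[2],
              gamma = 180 * genome[3])
  primary <- list(I = matrix(w[4:9], 3, 2),
                  O = matrix(w[10:21], 3, 4))
  secondary <- list(I = matrix(w[22:27], 3, 2),
                    O = matrix(w[28:31], 1, 4))
  list(angles = angles, primary = primary, secondary = secondary,
       markers = genome[32:34])
}

#' Evaluate a growth-policy network
#'
#' Hidden activations are `tanh(gain * I %*% x)`, extended with a constant
#' unit bias signal; outputs are the linear combination `O %*% c(hidden,
#' 1)`.
#'
#' @param net a `list(I, O)` as returned by [decode_genome()].
#' @param inputs numeric input vector of order-1 magnitudes.
#' @param gain hidden-layer gain.
#' @return Numeric output vector.
#' @export
nn_eval <- function(net, inputs, gain = 5) {
  if (length(inputs) != ncol(net$I)) stop("input dimension mismatch")
  hidden <- tanh(gain * as.vector(net$I %*% inputs))
  as.vector(net$O %*% c(hidden, 1))
}

# Bounded order-1 scalings of the raw physiological state.
scale_volume <- function(v_over_v0) log10(1 + v_over_v0) / 3
scale_count <- function(n) log10(1 + n) / 3

#' Primary-growth policy
#'
#' Maps the tree state (reserve volume and foliage count) to the carbon
#' proportions allocated to new segments (`P_seg`) and seeds (`P_seed`),
#' with `P_seg + P_seed <= 1`, and a photosensitivity `p` in `[0, 1]`.
#' Raw outputs `z` are squashed by `u = (1 + tanh(z)) / 2`, then
#' `P_seg = u1 (1 - u2)`, `P_seed = u1 u2`, `p = u3`, which enforces the
#' simplex constraint by construction.
#'
#' @param reserve reserve volume.
#' @param n_foliages number of foliages of the tree.
#' @param net the decoded primary network.
#' @param params a [wt_params()] object.
#' @return Named numeric vector `c(P_seg, P_seed, p)`.
#' @export
primary_policy <- function(reserve, n_foliages, net,
                           params = wt_params()) {
  x <- c(scale_volume(reserve / params$V0), scale_count(n_foliages))
  u <- (1 + tanh(nn_eval(net, x, params$nn_gain))) / 2
  c(P_seg = u[1] * (1 - u[2]), P_seed = u[1] * u[2], p = u[3])
}

#' Secondary-growth policy (thigmomorphogenetic safety factor)
#'
#' Maps a segment's sensed relative stress and the number of foliages it
#' irrigates to a safety factor `S` in `[1, 6]` through the logistic
#' squashing `S = 1 + 5 (1 + tanh(z)) / 2`; a zero-weight genome gives
#' the midpoint `S = 3.5`.
#'
#' @param sigma_rel `sigma_max / sigma0`, clipped to `[0, 2]` on input.
#' @param n_foliages_above number of descendant foliages.
#' @param net the decoded secondary network.
#' @param params a [wt_params()] object.
#' @return Safety factor(s) in `[1, 6]` (vectorised over segments).
#' @export
secondary_policy <- function(sigma_rel, n_foliages_above, net,
                             params = wt_params()) {
  x1 <- pmin(pmax(sigma_rel, 0), 2)
  x2 <- scale_count(n_foliages_above)
  g <- params$nn_gain
  hidden <- tanh(g * (outer(net$I[, 1], x1) + outer(net$I[, 2], x2)))
  z <- as.vector(net$O[1, 1:3] %*% hidden) + net$O[1, 4]
  1 + 5 * (1 + tanh(z)) / 2
}

#' Mutate a genome
#'
#' With probability `p_mut` each gene (neutral markers included) is
#' replaced by `g + eps * delta_g` with `eps` standard normal, then
#' clamped to `[0, 1]`.
#'
#' @param genome numeric vector of 34 genes.
#' @param params a [wt_params()] object supplying `p_mut` and `delta_g`.
#' @return The mutated genome.
#' @export
mutate_genome <- function(genome, params = wt_params()) {
  hit <- runif(length(genome)) < params$p_mut
  if (any(hit))
    genome[hit] <- pmin(pmax(
      genome[hit] + rnorm(sum(hit)) * params$delta_g, 0), 1)
  genome
}

#' Write / read genome files
#'
#' One genome per line, 34 comma-separated values in `[0, 1]`; the format
#' used for tournament winner pools.
#'
#' @param genomes a genome vector or matrix (one row per genome).
#' @param path file path.
#' @return `write_genomes` returns `path` invisibly; `read_genomes`
#'   returns a matrix with one genome per row.
#' @export
write_genomes <- function(genomes, path) {
  if (is.null(dim(genomes))) genomes <- matrix(genomes, 1)
  lines <- apply(genomes, 1, function(g)
    paste(sprintf("%.17g", g), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genomes
#' @export
read_genomes <- function(path) {
  lines <- readLines(path)
  g <- do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
  if (ncol(g) != GENOME_LENGTH)
    stop("expected ", GENOME_LENGTH, " genes per line")
  g
}
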