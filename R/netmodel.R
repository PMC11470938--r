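#' Bilateral HS-H2-bIPS-uLPTCrn network configuration
#'
#' A linear steady-state rate network of 8 cells (4 types x 2 hemispheres)
#' driven by per-eye motion signals, with ohmic (Laplacian) gap-junction
#' coupling between each HS cell and the contralateral H2. The default
#' chemical motif is a left-right mirror-symmetric assumption set:
#' * HS_h <- ipsilateral FtB (+w) and BtF (-w): opponent drive;
#' * H2_h <- ipsilateral BtF (+1) plus 0.1 x contralateral FtB (H2 receives
#'   weaker frontal input from the other eye);
#' * contralateral chemical input to HS = 0 (contralateral BtF information
#'   reaches HS only through the gap junction);
#' * bIPS_h <- contralateral H2 (+1); uLPTCrn_h <- ipsilateral HS (+1) and
#'   ipsilateral bIPS (-1) (disinhibitory motif).
#'
#' @param g gap-junction conductance (>= 0, default 0.5) applied to both
#'   HS_L-H2_R and HS_R-H2_L edges.
#' @param w_ipsi_to_hs magnitude of the ipsilateral opponent drive onto HS
#'   (default 0.8; chosen so the gap-coupled H2 forward/backward response
#'   crossing lies outside the studied conductance range, keeping the DI
#'   monotone in g over `[0, 1]` for every cell).
#' @param w_contra_ftb_to_h2 contralateral FtB drive weight onto H2
#'   (default 0.1).
#' @param w_contra_to_hs contralateral chemical drive onto HS (default 0).
#' @param w_h2_to_bips,w_hs_to_ulptcrn,w_bips_to_ulptcrn chemical weights of
#'   the disinhibitory branch.
#' @param rectify half-wave rectify responses (fixed-point iteration;
#'   default FALSE = linear solve).
#' @return list of class `network_config`: `cells` (8 names), `W` (8x8
#'   chemical weight matrix, `W[i, j]` = weight from j onto i), `gap_edges`
#'   (data.frame a, b, g), `D` (8x4 drive matrix over inputs
#'   `sL_FtB, sL_BtF, sR_FtB, sR_BtF`), `rectify`.
#' @export
network_config <- function(g = 0.5, w_ipsi_to_hs = 0.8,
                           w_contra_ftb_to_h2 = 0.1,
                           w_contra_to_hs = 0, w_h2_to_bips = 1,
                           w_hs_to_ulptcrn = 1, w_bips_to_ulptcrn = 0.8,
                           rectify = FALSE) {
  stopifnot(g >= 0)
  cells <- c("HS_L", "H2_L", "bIPS_L", "uLPTCrn_L",
             "HS_R", "H2_R", "bIPS_R", "uLPTCrn_R")
  inputs <- c("sL_FtB", "sL_BtF", "sR_FtB", "sR_BtF")
  W <- matrix(0, 8, 8, dimnames = list(cells, cells))
  W["bIPS_L", "H2_R"] <- w_h2_to_bips
  W["bIPS_R", "H2_L"] <- w_h2_to_bips
  W["uLPTCrn_L", "HS_L"] <- w_hs_to_ulptcrn
  W["uLPTCrn_R", "HS_R"] <- w_hs_to_ulptcrn
  W["uLPTCrn_L", "bIPS_L"] <- -w_bips_to_ulptcrn
  W["uLPTCrn_R", "bIPS_R"] <- -w_bips_to_ulptcrn
  D <- matrix(0, 8, 4, dimnames = list(cells, inputs))
  D["HS_L", "sL_FtB"] <- w_ipsi_to_hs; D["HS_L", "sL_BtF"] <- -w_ipsi_to_hs
  D["HS_R", "sR_FtB"] <- w_ipsi_to_hs; D["HS_R", "sR_BtF"] <- -w_ipsi_to_hs
  D["HS_L", c("sR_FtB", "sR_BtF")] <- w_contra_to_hs
  D["HS_R", c("sL_FtB", "sL_BtF")] <- w_contra_to_hs
  D["H2_L", "sL_BtF"] <- 1; D["H2_L", "sR_FtB"] <- w_contra_ftb_to_h2
  D["H2_R", "sR_BtF"] <- 1; D["H2_R", "sL_FtB"] <- w_contra_ftb_to_h2
  gap_edges <- data.frame(a = c("HS_L", "HS_R"), b = c("H2_R", "H2_L"),
                          g = g)
  structure(list(cells = cells, inputs = inputs, W = W,
                 gap_edges = gap_edges, D = D, rectify = rectify),
            class = "network_config")
}

# graph Laplacian of the gap edges: +g on both diagonals, -g off-diagonal
.gap_laplacian <- function(config) {
  n <- length(config$cells)
  L <- matrix(0, n, n, dimnames = list(config$cells, config$cells))
  for (k in seq_len(nrow(config$gap_edges))) {
    a <- config$gap_edges$a[k]; b <- config$gap_edges$b[k]
    g <- config$gap_edges$g[k]
    L[a, a] <- L[a, a] + g; L[b, b] <- L[b, b] + g
    L[a, b] <- L[a, b] - g; L[b, a] <- L[b, a] - g
  }
  L
}

#' Per-eye drive vectors of the four optic-flow conditions
#'
#' Under the package's CCW-positive convention (see
#' [local_motion_direction()]): clockwise rotation gives the left eye BtF and
#' the right eye FtB; counterclockwise is the mirror image; forward
#' translation gives both eyes FtB; backward both BtF. Each drive has total
#' input mass 2.
#'
#' @return 4x4 numeric matrix, rows = conditions (`clockwise`,
#'   `counterclockwise`, `forward_translation`, `backward_translation`),
#'   columns = inputs (`sL_FtB, sL_BtF, sR_FtB, sR_BtF`).
#' @export
condition_drives <- function() {
  m <- rbind(clockwise = c(0, 1, 1, 0),
             counterclockwise = c(1, 0, 0, 1),
             forward_translation = c(1, 0, 1, 0),
             backward_translation = c(0, 1, 0, 1))
  colnames(m) <- c("sL_FtB", "sL_BtF", "sR_FtB", "sR_BtF")
  m
}

#' Steady-state network response to one drive
#'
#' Solves `(I - W + L_g) V = D s`, where `L_g` is the gap-edge Laplacian:
#' each cell's rate balances its chemical input, its drive and the ohmic gap
#' current `g (V_j - V_i)`. With `rectify = TRUE` the fixed point
#' `V = max(0, (W - L_g) V + D s)` is found by iteration (tolerance 1e-9,
#' at most 1e4 iterations).
#'
#' @param config a [network_config()].
#' @param drive length-4 input vector `(sL_FtB, sL_BtF, sR_FtB, sR_BtF)`.
#' @return named numeric vector of 8 steady-state responses.
#' @export
solve_network <- function(config, drive) {
  stopifnot(inherits(config, "network_config"), length(drive) == 4)
  L <- .gap_laplacian(config)
  A <- diag(8) - config$W + L
  b <- as.numeric(config$D %*% drive)
  if (!config$rectify) {
    if (rcond(A) < 1e-12)
      stop("singular steady-state system: check weights and conductances")
    v <- solve(A, b)
  } else {
    # damped fixed-point iteration; plain iteration can diverge when the
    # gap Laplacian pushes the recurrence spectral radius past 1
    v <- numeric(8)
    alpha <- 0.25
    for (it in seq_len(10000L)) {
      v_new <- (1 - alpha) * v +
        alpha * pmax(0, as.numeric((config$W - L) %*% v) + b)
      if (max(abs(v_new - v)) < 1e-9 * alpha) { v <- v_new; break }
      v <- v_new
      if (it == 10000L) stop("rectified fixed point did not converge")
    }
  }
  stats::setNames(as.numeric(v), config$cells)
}

#' Responses to the four optic-flow conditions
#'
#' @param config a [network_config()].
#' @return 8x4 matrix: rows cells, columns conditions.
#' @export
condition_responses <- function(config) {
  dr <- condition_drives()
  out <- vapply(rownames(dr), function(cd) solve_network(config, dr[cd, ]),
                numeric(8))
  out
}

#' Discrimination Index between translation and rotation
#'
#' Per cell, `OF_rot = max(cw, ccw) - min(cw, ccw)` and
#' `OF_trans = max(fwd, bwd) - min(fwd, bwd)`;
#' `DI = (OF_trans - OF_rot) / (|OF_trans| + |OF_rot|)`, in `[-1, 1]`:
#' +1 = purely translation-selective, -1 = purely rotation-selective. If both
#' ranges are zero the DI is defined as 0 and flagged degenerate.
#'
#' @param responses 8x4 matrix from [condition_responses()] (or any cells x
#'   conditions matrix with the four condition columns).
#' @return data.frame: `cell`, `of_rotation`, `of_translation`, `di`,
#'   `degenerate`.
#' @export
discrimination_index <- function(responses) {
  cw <- responses[, "clockwise"]; ccw <- responses[, "counterclockwise"]
  fw <- responses[, "forward_translation"]
  bw <- responses[, "backward_translation"]
  of_rot <- pmax(cw, ccw) - pmin(cw, ccw)
  of_tr <- pmax(fw, bw) - pmin(fw, bw)
  den <- abs(of_tr) + abs(of_rot)
  di <- ifelse(den > 0, (of_tr - of_rot) / den, 0)
  data.frame(cell = rownames(responses), of_rotation = of_rot,
             of_translation = of_tr, di = di, degenerate = den == 0,
             row.names = NULL)
}

#' Perturb the network
#'
#' Modes mirror the experimental manipulations:
#' * `silence_HS_chem` / `silence_H2_chem`: zero the cell type's chemical
#'   OUTPUT weights (gap edges kept);
#' * `shakB`: all gap conductances set to 0 (the innexin mutant);
#' * `kir_HS`: chemical and gap outputs of HS cells removed (silencing).
#'
#' Returns a modified copy; idempotent.
#'
#' @param config a [network_config()].
#' @param mode perturbation name.
#' @return modified `network_config`.
#' @export
perturb <- function(config, mode = c("silence_HS_chem", "silence_H2_chem",
                                     "shakB", "kir_HS")) {
  mode <- match.arg(mode)
  out <- config
  hs <- c("HS_L", "HS_R"); h2 <- c("H2_L", "H2_R")
  if (mode == "silence_HS_chem") {
    out$W[, hs] <- 0
  } else if (mode == "silence_H2_chem") {
    out$W[, h2] <- 0
  } else if (mode == "shakB") {
    out$gap_edges$g <- 0
  } else if (mode == "kir_HS") {
    out$W[, hs] <- 0
    keep <- !(out$gap_edges$a %in% hs | out$gap_edges$b %in% hs)
    out$gap_edges <- out$gap_edges[keep, , drop = FALSE]
  }
  out
}

#' DI as a function of gap-junction conductance
#'
#' Sweeps the gap conductance and returns the per-cell DI at each value;
#' under the default configuration the DI is non-increasing in `g` for every
#' cell (gap junctions make every cell more rotation-selective). Values where
#' the linear system is unstable are flagged.
#'
#' @param config a [network_config()] (its `g` is overridden).
#' @param g_values sorted non-negative conductances.
#' @return data.frame: `g`, `cell`, `di`, `ok`.
#' @export
di_vs_g_sweep <- function(config, g_values = seq(0, 1, by = 0.1)) {
  stopifnot(all(g_values >= 0), !is.unsorted(g_values))
  rows <- lapply(g_values, function(g) {
    cf <- config
    cf$gap_edges$g <- g
    di <- tryCatch(discrimination_index(condition_responses(cf)),
                   error = function(e) NULL)
    if (is.null(di))
      return(data.frame(g = g, cell = config$cells, di = NA_real_,
                        ok = FALSE))
    data.frame(g = g, cell = di$cell, di = di$di, ok = TRUE)
  })
  do.call(rbind, rows)
}

#' Write / read a network configuration as JSON
#'
#' @param config a [network_config()].
#' @param path file path.
#' @return `path` (write) or a `network_config` (read).
#' @export
write_network_config <- function(config, path) {
  payload <- list(cells = config$cells, inputs = config$inputs,
                  W = config$W, gap_edges = config$gap_edges,
                  D = config$D, rectify = config$rectify)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(as.numeric(p$W), 8, 8, byrow = FALSE,
              dimnames = list(p$cells, p$cells))
  D <- matrix(as.numeric(p$D), 8, 4, byrow = FALSE,
              dimnames = list(p$cells, p$inputs))
  structure(list(cells = p$cells, inputs = p$inputs, W = W,
                 gap_edges = as.data.frame(p$gap_edges), D = D,
                 rectify = isTRUE(p$rectify)),
            class = "network_config")
}
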