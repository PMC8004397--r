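#' Configuration for the synthetic thymocyte dataset
#'
#' Builds the configuration object consumed by [simulate_dataset()]. The
#' defaults emulate the developmental structure of mouse double-positive
#' (DP) thymocyte maturation: a linear chain
#' DN -> ISP -> DPbla -> DPre -> DPsel that bifurcates into the two
#' single-positive fates CD4sp and CD8sp, with stage-specific marker
#' programs, five cell-cycle phase programs (G1/S, S, G2/M, M, M/G1),
#' and per-stage proliferation regimes. Under the default regimes the
#' early stages (DN, ISP) cycle with randomly ordered phases, the DP
#' blast stage cycles with phases laid out sequentially along the
#' within-stage order (the proliferation mode under study), and the
#' post-blast stages are quiescent.
#'
#' @param stages Character vector of linear-chain stage names, ordered from
#'   the progenitor to the last pre-branch stage.
#' @param branches Character vector (length 2) of terminal branch stage
#'   names sharing the final trajectory segment.
#' @param cells_per_stage Cells simulated per stage (each branch counts as
#'   one stage).
#' @param markers_per_stage Number of stage-specific marker genes per stage.
#' @param phase_genes_per_phase Number of periodic genes per cell-cycle
#'   phase.
#' @param regime Named character vector mapping every stage (including
#'   branches) to one of `"sequential"`, `"continuous"`, `"noncycling"`.
#'   Stages not named default to `"noncycling"`.
#' @param nb_mean_high,nb_mean_low Negative-binomial mean of a program gene
#'   inside/outside its active program.
#' @param nb_dispersion Negative-binomial size (dispersion) parameter;
#'   `Inf` gives Poisson counts.
#' @param dropout_rate Probability that any count entry is independently
#'   zeroed after sampling.
#' @param n_gradient_genes Number of maturation-gradient genes: genes
#'   switching on (half) or off (half) at sigmoid steps whose centers
#'   are spread evenly along the trajectory interior. They emulate the
#'   continuous developmental programs running through every stage and
#'   are the planted "dynamically varying" genes with known switch
#'   positions.
#' @param n_background_genes,n_mito_genes,n_ribo_genes,n_pseudo_genes
#'   Numbers of unstructured background, mitochondrial (`mt-` prefixed),
#'   ribosomal (`Rps`/`Rpl` prefixed) and pseudogene features.
#' @param mito_fraction_outliers Number of cells planted with a
#'   mitochondrial count fraction above 40% (QC positives).
#' @param low_complexity_outliers Number of cells planted with globally
#'   depressed expression so that very few genes are detected.
#' @param ramp_width Width, in trajectory-order units, of the sigmoid
#'   on/off ramps of stage marker programs (keeps adjacent stages
#'   connected in expression space).
#' @param phase_bump_sd Standard deviation, in cycle-coordinate units,
#'   of the Gaussian activation bump of each phase program.
#' @param residual_decay Decay length, in trajectory-order units, of the
#'   residual cycle program carried by cells of a quiescent stage that
#'   directly follows a cycling stage.
#' @param seed Integer seed; regeneration with the same seed is
#'   byte-identical.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_dataset()], [write_fixture()]
#' @export
sim_config <- function(stages = c("DN", "ISP", "DPbla", "DPre", "DPsel"),
                       branches = c("CD4sp", "CD8sp"),
                       cells_per_stage = 300L,
                       markers_per_stage = 20L,
                       phase_genes_per_phase = 20L,
                       regime = c(DN = "continuous", ISP = "continuous",
                                  DPbla = "sequential"),
                       nb_mean_high = 20,
                       nb_mean_low = 0.2,
                       nb_dispersion = 5,
                       dropout_rate = 0.1,
                       n_gradient_genes = 100L,
                       n_background_genes = 100L,
                       n_mito_genes = 10L,
                       n_ribo_genes = 10L,
                       n_pseudo_genes = 5L,
                       mito_fraction_outliers = 0L,
                       low_complexity_outliers = 0L,
                       ramp_width = 0.01,
                       phase_bump_sd = 0.10,
                       residual_decay = 0.02,
                       seed = 1L) {
  if (length(stages) < 1L) stop("'stages' must be non-empty", call. = FALSE)
  if (length(branches) != 2L)
    stop("'branches' must name exactly two terminal fates", call. = FALSE)
  all_stages <- c(stages, branches)
  if (anyDuplicated(all_stages))
    stop("stage names must be unique", call. = FALSE)
  assert_scalar_num(cells_per_stage, "cells_per_stage", positive = TRUE)
  assert_scalar_num(markers_per_stage, "markers_per_stage", positive = TRUE)
  assert_scalar_num(phase_genes_per_phase, "phase_genes_per_phase",
                    positive = TRUE)
  assert_scalar_num(nb_mean_high, "nb_mean_high", positive = TRUE)
  assert_scalar_num(nb_mean_low, "nb_mean_low", positive = TRUE)
  assert_scalar_num(nb_dispersion, "nb_dispersion", positive = TRUE)
  assert_scalar_num(dropout_rate, "dropout_rate")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("'dropout_rate' must lie in [0, 1]", call. = FALSE)

  full_regime <- setNames(rep("noncycling", length(all_stages)), all_stages)
  if (length(regime)) {
    if (is.null(names(regime)))
      stop("'regime' must be a named vector", call. = FALSE)
    unknown <- setdiff(names(regime), all_stages)
    if (length(unknown))
      stop("regime given for unknown stage(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad <- !regime %in% c("sequential", "continuous", "noncycling")
    if (any(bad))
      stop("invalid regime '", regime[bad][1L], "' for stage '",
           names(regime)[bad][1L],
           "' (must be sequential, continuous or noncycling)", call. = FALSE)
    full_regime[names(regime)] <- regime
  }

  structure(list(
    stages = stages, branches = branches,
    cells_per_stage = as.integer(cells_per_stage),
    markers_per_stage = as.integer(markers_per_stage),
    phase_genes_per_phase = as.integer(phase_genes_per_phase),
    regime = full_regime,
    nb_mean_high = nb_mean_high, nb_mean_low = nb_mean_low,
    nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
    n_gradient_genes = as.integer(n_gradient_genes),
    n_background_genes = as.integer(n_background_genes),
    n_mito_genes = as.integer(n_mito_genes),
    n_ribo_genes = as.integer(n_ribo_genes),
    n_pseudo_genes = as.integer(n_pseudo_genes),
    mito_fraction_outliers = as.integer(mito_fraction_outliers),
    low_complexity_outliers = as.integer(low_complexity_outliers),
    ramp_width = ramp_width, phase_bump_sd = phase_bump_sd,
    residual_decay = residual_decay,
    seed = as.integer(seed)
  ), class = "sim_config")
}

phase_codes <- function() c("G1S", "S", "G2M", "M", "MG1")

# Deterministic mean structure of the simulation: cell metadata and the
# genes x cells matrix of negative-binomial means (before count sampling).
# RNG is only used for cell positions, continuous-regime phase draws and
# outlier-cell selection; call under with_seed().
sim_mean_structure <- function(config) {
  chain <- config$stages
  branches <- config$branches
  n_chain <- length(chain)
  depth <- n_chain + 1L               # branch stages share the last segment
  w <- 1 / depth
  cps <- config$cells_per_stage
  all_stages <- c(chain, branches)

  # per-stage trajectory intervals [a, b]
  a <- c((seq_len(n_chain) - 1L) * w, rep(n_chain * w, 2L))
  b <- c(seq_len(n_chain) * w, rep(1, 2L))
  names(a) <- names(b) <- all_stages

  cells <- do.call(rbind, lapply(seq_along(all_stages), function(si) {
    st <- all_stages[si]
    u <- sort(runif(cps, min = a[st], max = b[st]))
    data.frame(stage = st, true_order = u,
               branch = if (st %in% branches) st else NA_character_,
               stringsAsFactors = FALSE)
  }))
  n_cells <- nrow(cells)
  cells$cell <- sprintf("cell%05d", seq_len(n_cells))
  rownames(cells) <- cells$cell
  v_within <- (cells$true_order - a[cells$stage]) /
    (b[cells$stage] - a[cells$stage])

  # Cell-cycle coordinate, program amplitude and true phase per cell.
  # Sequential stages traverse the cycle once along the within-stage
  # order; continuous stages draw a random cycle coordinate per cell
  # (phase uniform over the five phases, independent of the order; the
  # coordinate is circular, so cycling cells form a closed ring in
  # expression space). Cells of a quiescent stage that follows a cycling
  # stage keep an exponentially decaying residual of the exit-point
  # program — freshly post-mitotic cells do not shed cycle transcripts
  # instantaneously — which keeps expression continuous across the
  # cycle-exit boundary. Residual cells are still truly "none".
  ph <- phase_names()
  stage_of <- match(cells$stage, all_stages)
  # chain predecessor of each stage (branches follow the last chain stage)
  pred <- c(NA_integer_, seq_len(n_chain - 1L), n_chain, n_chain)
  cycle_pos <- rep(NA_real_, n_cells)
  cycle_amp <- rep(0, n_cells)
  cycle_wrap <- rep(FALSE, n_cells)
  for (st in all_stages) {
    idx <- which(cells$stage == st)
    reg <- config$regime[[st]]
    if (reg == "sequential") {
      cycle_pos[idx] <- v_within[idx]
      cycle_amp[idx] <- 1
    } else if (reg == "continuous") {
      cycle_pos[idx] <- runif(length(idx))
      cycle_amp[idx] <- 1
      cycle_wrap[idx] <- TRUE
    } else {
      pst <- pred[match(st, all_stages)]
      if (!is.na(pst) && config$regime[[all_stages[pst]]] != "noncycling") {
        prev_reg <- config$regime[[all_stages[pst]]]
        cycle_amp[idx] <- exp(-(cells$true_order[idx] - a[st]) /
                                config$residual_decay)
        if (prev_reg == "sequential") {
          cycle_pos[idx] <- 1
        } else {
          cycle_pos[idx] <- runif(length(idx))
          cycle_wrap[idx] <- TRUE
        }
      }
    }
  }
  cycling <- cycle_amp == 1
  true_phase <- ifelse(cycling,
                       ph[pmin(5L, pmax(1L, ceiling(cycle_pos * 5)))],
                       "none")
  cells$true_phase <- true_phase

  rw <- config$ramp_width
  lo <- config$nb_mean_low
  hi <- config$nb_mean_high
  u <- cells$true_order

  # gene catalogue
  marker_genes <- lapply(all_stages, function(st)
    sprintf("Mrk.%s.%02d", st, seq_len(config$markers_per_stage)))
  names(marker_genes) <- all_stages
  phase_gene_sets <- lapply(phase_codes(), function(pc)
    sprintf("Ccg.%s.%02d", pc, seq_len(config$phase_genes_per_phase)))
  names(phase_gene_sets) <- ph
  grad <- if (config$n_gradient_genes)
    sprintf("Dyn.%03d", seq_len(config$n_gradient_genes)) else character()
  bgd <- if (config$n_background_genes)
    sprintf("Bgd.%03d", seq_len(config$n_background_genes)) else character()
  mito <- if (config$n_mito_genes)
    sprintf("mt-Sim%02d", seq_len(config$n_mito_genes)) else character()
  ribo <- if (config$n_ribo_genes)
    sprintf("%s.sim%02d",
            rep_len(c("Rps", "Rpl"), config$n_ribo_genes),
            seq_len(config$n_ribo_genes)) else character()
  pseudo <- if (config$n_pseudo_genes)
    sprintf("Sim%02d-ps", seq_len(config$n_pseudo_genes)) else character()

  gene_names <- c(unlist(marker_genes, use.names = FALSE),
                  unlist(phase_gene_sets, use.names = FALSE),
                  grad, bgd, mito, ribo, pseudo)
  n_genes <- length(gene_names)
  gene_ids <- sprintf("SIMG%05d", seq_len(n_genes))

  mu <- matrix(lo, nrow = n_genes, ncol = n_cells,
               dimnames = list(gene_names, cells$cell))

  # stage marker programs: sigmoid on/off ramps along the global order
  switches <- list()
  for (si in seq_along(all_stages)) {
    st <- all_stages[si]
    is_branch <- st %in% branches
    # branch programs turn on *inside* the branch segment (center shifted
    # by 3 ramp widths) so expression is continuous across the bifurcation
    on_center <- if (is_branch) a[st] + 3 * rw else a[st]
    on_ramp <- if (a[st] == 0) rep(1, n_cells) else
      stats::plogis((u - on_center) / rw)
    off_ramp <- if (b[st] == 1) rep(1, n_cells) else
      1 - stats::plogis((u - b[st]) / rw)
    act <- on_ramp * off_ramp
    if (is_branch)                        # branch program only on own branch
      act <- act * as.numeric(!is.na(cells$branch) & cells$branch == st)
    mu[marker_genes[[st]], ] <-
      rep(lo + (hi - lo) * act, each = length(marker_genes[[st]]))
    if (a[st] > 0)
      switches[[length(switches) + 1L]] <-
        data.frame(gene = marker_genes[[st]],
                   position = unname(on_center), sign = 1L)
    if (b[st] < 1)
      switches[[length(switches) + 1L]] <-
        data.frame(gene = marker_genes[[st]],
                   position = unname(b[st]), sign = -1L)
  }
  switches <- do.call(rbind, switches)

  # cell-cycle phase programs: amplitude-modulated Gaussian bumps over
  # the cycle coordinate (wrapped distance for ring coordinates)
  centers <- (seq_len(5L) - 0.5) / 5
  tau <- config$phase_bump_sd
  has_cycle <- which(cycle_amp > 1e-6)
  if (length(has_cycle)) {
    for (q in seq_len(5L)) {
      dist_q <- abs(cycle_pos[has_cycle] - centers[q])
      dist_q <- ifelse(cycle_wrap[has_cycle], pmin(dist_q, 1 - dist_q),
                       dist_q)
      act <- cycle_amp[has_cycle] * exp(-dist_q^2 / (2 * tau^2))
      mu[phase_gene_sets[[ph[q]]], has_cycle] <-
        rep(lo + (hi - lo) * act, each = config$phase_genes_per_phase)
    }
  }

  # maturation-gradient genes: hard expression steps with centers spread
  # evenly over the trajectory interior, alternating turn-on / turn-off
  if (length(grad)) {
    ng <- length(grad)
    grad_pos <- 0.05 + 0.9 * (seq_len(ng) - 0.5) / ng
    grad_sign <- rep_len(c(1L, -1L), ng)
    for (gi in seq_len(ng)) {
      act <- as.numeric(u > grad_pos[gi])
      if (grad_sign[gi] < 0) act <- 1 - act
      mu[grad[gi], ] <- lo + (hi - lo) * act
    }
    switches <- rbind(switches,
                      data.frame(gene = grad, position = grad_pos,
                                 sign = grad_sign))
  }

  if (length(bgd)) mu[bgd, ] <- 1
  if (length(mito)) mu[mito, ] <- 5
  if (length(ribo)) mu[ribo, ] <- 5
  if (length(pseudo)) mu[pseudo, ] <- 1

  # planted QC outliers
  mito_out <- integer()
  if (config$mito_fraction_outliers > 0L && length(mito)) {
    mito_out <- sample(n_cells, config$mito_fraction_outliers)
    mu[mito, mito_out] <- mu[mito, mito_out] * 50
  }
  low_out <- integer()
  if (config$low_complexity_outliers > 0L) {
    pool <- setdiff(seq_len(n_cells), mito_out)
    low_out <- sample(pool, config$low_complexity_outliers)
    mu[, low_out] <- mu[, low_out] * 0.02
  }

  list(mu = mu, cells = cells, switches = switches,
       gene_ids = gene_ids, gene_names = gene_names,
       marker_genes = marker_genes, phase_gene_sets = phase_gene_sets,
       gradient_genes = grad,
       pseudo_ids = gene_ids[match(pseudo, gene_names)],
       mito_outlier_cells = cells$cell[mito_out],
       low_complexity_cells = cells$cell[low_out])
}

#' Simulate a thymocyte development count matrix with ground truth
#'
#' Draws a sparse genes x cells matrix of negative-binomial counts with
#' Bernoulli dropout over the deterministic mean structure defined by a
#' [sim_config()]: stage marker programs ramping on and off along the
#' trajectory order, cell-cycle phase programs under the per-stage
#' proliferation regime, unstructured background genes, and flagged
#' mitochondrial / ribosomal / pseudogene blocks for QC testing.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_dataset` with elements
#'   \describe{
#'     \item{counts}{A `count_matrix` (see [load_counts()]) of simulated
#'       counts.}
#'     \item{truth}{Ground truth: `cells` (cell, stage, true_order,
#'       true_phase, branch), `switches` (gene, position, sign of each
#'       planted expression step, strictly inside (0,1)),
#'       `marker_genes`, `phase_gene_sets`, `cellcycle_genes`,
#'       planted outlier cell ids and the generating `config`.}
#'   }
#' @examples
#' cfg <- sim_config(cells_per_stage = 30, seed = 7)
#' ds <- simulate_dataset(cfg)
#' dim(ds$counts$counts)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object", call. = FALSE)
  with_seed(config$seed, {
    str <- sim_mean_structure(config)
    mu <- str$mu
    n <- length(mu)
    counts <- if (is.infinite(config$nb_dispersion))
      rpois(n, lambda = as.vector(mu))
    else
      rnbinom(n, size = config$nb_dispersion, mu = as.vector(mu))
    if (config$dropout_rate > 0)
      counts <- counts * rbinom(n, 1L, 1 - config$dropout_rate)
    cm <- matrix(counts, nrow = nrow(mu), dimnames = dimnames(mu))
    cmat <- count_matrix(as(as(Matrix::Matrix(cm, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix"),
                         gene_ids = str$gene_ids,
                         gene_names = str$gene_names,
                         barcodes = str$cells$cell,
                         pseudogene_ids = str$pseudo_ids)
    structure(list(
      counts = cmat,
      truth = list(cells = str$cells, switches = str$switches,
                   marker_genes = str$marker_genes,
                   phase_gene_sets = str$phase_gene_sets,
                   gradient_genes = str$gradient_genes,
                   cellcycle_genes = unlist(str$phase_gene_sets,
                                            use.names = FALSE),
                   mito_outlier_cells = str$mito_outlier_cells,
                   low_complexity_cells = str$low_complexity_cells,
                   config = config)
    ), class = "sim_dataset")
  })
}

#' Write a simulated dataset as a 10x-style fixture
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate, 1-based),
#' `barcodes.tsv`, `features.tsv` (id, name), `truth.tsv` (cell, stage,
#' true_order, true_phase, branch) and, when pseudogenes are present,
#' `pseudogenes.tsv`. The file set round-trips losslessly through
#' [load_counts()].
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_fixture <- function(dataset, directory) {
  if (!inherits(dataset, "sim_dataset"))
    stop("'dataset' must come from simulate_dataset()", call. = FALSE)
  m <- dataset$counts
  if (nrow(m$counts) == 0L)
    stop("dataset has an empty gene set; nothing to write", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(directory, "matrix.mtx"),
             barcodes = file.path(directory, "barcodes.tsv"),
             features = file.path(directory, "features.tsv"),
             truth = file.path(directory, "truth.tsv"))
  Matrix::writeMM(m$counts, paths[["matrix"]])
  writeLines(m$barcodes, paths[["barcodes"]])
  write.table(data.frame(m$gene_ids, m$gene_names),
              paths[["features"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(dataset$truth$cells[, c("cell", "stage", "true_order",
                                      "true_phase", "branch")],
              paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  pseudo <- m$gene_ids[m$gene_flags$pseudogene]
  if (length(pseudo)) {
    paths[["pseudogenes"]] <- file.path(directory, "pseudogenes.tsv")
    writeLines(pseudo, paths[["pseudogenes"]])
  }
  invisible(paths)
}
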