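#' Family specification for the timecourse simulator
#'
#' Describes one cell family: its name, its characteristic marker genes and
#' the generative mean fold by which those markers are elevated over their
#' baseline in cells of the family. The mesenchymal progenitor family may
#' additionally carry a `subtypes` block describing a differentiation
#' continuum (tenocyte / MSC / chondrocyte / preosteoblast): per-subtype
#' boolean marker programs, per-day mixing weights, and a Vegfa mean per
#' (subtype, day).
#'
#' @param name family label.
#' @param markers character vector of marker gene names (elevated in this
#'   family only).
#' @param marker_fold generative mean fold (> 1) of markers vs their
#'   baseline.
#' @param subtypes optional list with elements `programs` (named list of
#'   positive-marker gene vectors per subtype), `weights` (subtype x day
#'   matrix of mixing proportions, columns named by day, each column summing
#'   to 1), `vegfa` (subtype x day matrix of Vegfa generative means) and
#'   `program_level` (generative mean, in baseline-relative units, of a
#'   program gene in cells of the expressing subtype).
#' @return a `FamilySpec` list.
#' @export
familySpec <- function(name, markers, marker_fold = 5, subtypes = NULL) {
    if (!length(markers)) stopf("family '%s' has no marker genes", name)
    if (marker_fold <= 1) stopf("marker_fold must exceed 1")
    if (!is.null(subtypes)) {
        w <- subtypes$weights
        if (is.null(w) || is.null(subtypes$programs))
            stopf("subtypes need 'programs' and 'weights'")
        if (any(abs(colSums(w) - 1) > 1e-8))
            stopf("subtype weights must sum to 1 within each day")
        if (!setequal(rownames(w), names(subtypes$programs)))
            stopf("subtype weights rows must match program names")
        if (is.null(subtypes$program_level)) subtypes$program_level <- 2
    }
    structure(list(name = name, markers = unique(markers),
                   marker_fold = marker_fold, subtypes = subtypes),
              class = "FamilySpec")
}

# subtype programs used both by the generator and by the default gating
# rules, so that noise-free gating recovers the planted labels exactly
.subtypePrograms <- list(
    tenocyte      = c("Scx", "Col1a1"),
    MSC           = c("Pdgfra"),
    chondrocyte   = c("Sox9", "Acan", "Col1a1", "Col3a1"),
    preosteoblast = c("Runx2", "Col1a1"))

.defaultSubtypes <- function() {
    days <- c(0, 3, 7, 21)
    w <- rbind(
        tenocyte      = c(0.40, 0.150, 0.118, 0.13),
        MSC           = c(0.50, 0.550, 0.477, 0.40),
        chondrocyte   = c(0.02, 0.100, 0.098, 0.12),
        preosteoblast = c(0.08, 0.200, 0.307, 0.35))
    colnames(w) <- days
    # Vegfa generative means (baseline-relative units): progenitors peak at
    # day 3 and attenuate by day 7; preosteoblasts sustain through day 21;
    # tenocytes carry a low early signal that fades.
    v <- rbind(
        tenocyte      = c(1.0, 0.8, 0.1, 0.1),
        MSC           = c(0.5, 3.0, 0.8, 0.5),
        chondrocyte   = c(0.3, 1.5, 0.5, 0.3),
        preosteoblast = c(0.3, 1.5, 1.5, 1.5))
    colnames(v) <- days
    list(programs = .subtypePrograms, weights = w, vegfa = v,
         program_level = 2)
}

# pad the published characteristic genes with synthetic family-private
# markers so each family carries the same number of elevated genes
.padMarkers <- function(core, name, n = 16) {
    extra <- sprintf("%s.m%02d", tolower(name), seq_len(max(0L, n - length(core))))
    c(core, extra)
}

#' Default seven-family specification
#'
#' Seven cell families with the characteristic markers used for identity
#' assignment (mesenchymal stem cells Pdgfra/Prrx1; satellite cells Pax7;
#' Schwann cells Plp1/Cnp/Dhh; myofibroblasts Acta2/Mylk;
#' endothelial/vascular progenitors Cdh5/Pecam1/Cd34; lymphocytes Ms4a1;
#' myeloid cells Ccr2/Mrc1/Fcgr1/Ccr1/S100a9/Cd209a), each padded with
#' synthetic family-private markers to `n_markers` genes. The mesenchymal
#' family carries the subtype continuum.
#'
#' @param marker_fold generative marker fold, shared by all families.
#' @param n_markers markers per family after padding.
#' @param shared_fraction fraction of the mesenchymal family's markers also
#'   given to the myofibroblast family, to emulate a pair of related
#'   progenitor families (0 = fully disjoint programs).
#' @return list of [familySpec()] objects named A-G by the labels used in
#'   identity assignment.
#' @export
defaultFamilies <- function(marker_fold = 5, n_markers = 16,
                            shared_fraction = 0) {
    fams <- list(
        familySpec("msc", .padMarkers(c("Pdgfra", "Prrx1"), "msc", n_markers),
                   marker_fold, subtypes = .defaultSubtypes()),
        familySpec("satellite", .padMarkers("Pax7", "satellite", n_markers),
                   marker_fold),
        familySpec("schwann", .padMarkers(c("Plp1", "Cnp", "Dhh"), "schwann",
                   n_markers), marker_fold),
        familySpec("myofibroblast", .padMarkers(c("Acta2", "Mylk"),
                   "myofibroblast", n_markers), marker_fold),
        familySpec("endothelial", .padMarkers(c("Cdh5", "Pecam1", "Cd34"),
                   "endothelial", n_markers), marker_fold),
        familySpec("lymphocyte", .padMarkers("Ms4a1", "lymphocyte",
                   n_markers), marker_fold),
        familySpec("myeloid", .padMarkers(c("Ccr2", "Mrc1", "Fcgr1", "Ccr1",
                   "S100a9", "Cd209a"), "myeloid", n_markers), marker_fold))
    names(fams) <- vapply(fams, `[[`, "", "name")
    if (shared_fraction > 0) {
        n_shared <- round(shared_fraction * n_markers)
        shared <- fams$msc$markers[seq_len(n_shared)]
        own <- setdiff(fams$myofibroblast$markers, shared)
        fams$myofibroblast$markers <-
            c(shared, own[seq_len(n_markers - n_shared)])
    }
    fams
}

.defaultComposition <- function() {
    m <- rbind(
        msc           = c(0.24, 0.28, 0.32, 0.28),
        satellite     = c(0.10, 0.08, 0.08, 0.10),
        schwann       = c(0.10, 0.08, 0.08, 0.08),
        myofibroblast = c(0.14, 0.10, 0.10, 0.12),
        endothelial   = c(0.15, 0.10, 0.10, 0.14),
        lymphocyte    = c(0.10, 0.10, 0.08, 0.10),
        myeloid       = c(0.17, 0.26, 0.24, 0.18))
    colnames(m) <- c(0, 3, 7, 21)
    m
}

#' Simulation configuration for the synthetic timecourse
#'
#' Fixes every generative parameter of the synthetic study: gene and cell
#' counts, the family structure, the day x family composition, the per-cell
#' sequencing-depth law (log-normal), the gene-level negative-binomial
#' dispersion, a per-replicate multiplicative log-normal batch effect, and
#' the mitochondrial-read fraction. A fixed `seed` fully determines the
#' output.
#'
#' @param n_genes total genes, including markers and mitochondrial genes.
#' @param families list of [familySpec()]s; default [defaultFamilies()].
#' @param timepoints integer days of the timecourse.
#' @param replicates_per_timepoint replicates per day.
#' @param cells_per_replicate cells per (day, replicate) unit.
#' @param composition families x days matrix of proportions; columns must
#'   sum to 1 and be named by day.
#' @param depth_mean median of the per-cell total-UMI log-normal law.
#' @param depth_dispersion sdlog of that law.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param batch_effect_sd sd of the per-replicate, per-gene log-normal
#'   multiplicative batch factor.
#' @param mito_fraction_range range of the per-cell mitochondrial UMI
#'   fraction (drawn uniformly).
#' @param n_mito number of mitochondrial genes (named `mt-*`).
#' @param exact if TRUE, produce noise-free matrices: counts equal the
#'   rounded expected counts, depth and mito fraction fixed at their
#'   central values (batch factors still drawn unless `batch_effect_sd` is
#'   0).
#' @param rogue optional list(day, replicate, n_cells): plant a
#'   replicate-private cluster of cells whose expression profile is an
#'   uncorrelated permutation of the baseline, for discard-rule validation.
#' @param allow_shared_markers permit overlapping family marker sets (used
#'   by related-family scenarios; rejected otherwise).
#' @param seed integer seed; fully determines the simulated data.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(n_genes = 800L,
                      families = defaultFamilies(),
                      timepoints = c(0L, 3L, 7L, 21L),
                      replicates_per_timepoint = 2L,
                      cells_per_replicate = 500L,
                      composition = .defaultComposition(),
                      depth_mean = 5000,
                      depth_dispersion = 0.3,
                      nb_dispersion = 0.5,
                      batch_effect_sd = 0.1,
                      mito_fraction_range = c(0.02, 0.08),
                      n_mito = 10L,
                      exact = FALSE,
                      rogue = NULL,
                      allow_shared_markers = FALSE,
                      seed = 1L) {
    if (!length(families)) stopf("at least one family is required")
    if (n_genes < 1 || cells_per_replicate < 1 ||
        replicates_per_timepoint < 1)
        stopf("all counts and dimensions must be positive")
    if (depth_mean <= 0 || depth_dispersion < 0 || nb_dispersion < 0 ||
        batch_effect_sd < 0)
        stopf("depth and dispersion parameters must be nonnegative")
    if (length(mito_fraction_range) != 2 ||
        any(mito_fraction_range < 0 | mito_fraction_range > 1) ||
        diff(mito_fraction_range) < 0)
        stopf("mito_fraction_range must be an interval within [0, 1]")
    fam_names <- vapply(families, `[[`, "", "name")
    if (anyDuplicated(fam_names)) stopf("family names must be unique")
    marker_sets <- lapply(families, `[[`, "markers")
    all_markers <- unlist(marker_sets)
    if (!allow_shared_markers && anyDuplicated(all_markers))
        stopf("family marker sets overlap; set allow_shared_markers = TRUE if intended")
    composition <- as.matrix(composition)
    if (is.null(colnames(composition))) {
        if (ncol(composition) != length(timepoints))
            stopf("composition needs a column per timepoint")
        colnames(composition) <- as.character(timepoints)
    }
    if (!all(as.character(timepoints) %in% colnames(composition)))
        stopf("composition needs a column per timepoint")
    if (is.null(rownames(composition)) ||
        !setequal(rownames(composition), fam_names))
        stopf("composition rows must match family names")
    comp <- composition[fam_names, as.character(timepoints), drop = FALSE]
    if (any(comp < 0 | comp > 1))
        stopf("composition proportions must lie in [0, 1]")
    if (any(abs(colSums(comp) - 1) > 1e-8))
        stopf("composition proportions must sum to 1 within each day")
    for (f in families) {
        if (!is.null(f$subtypes) &&
            !all(as.character(timepoints) %in% colnames(f$subtypes$weights)))
            stopf("subtype weights of family '%s' need a column per timepoint",
                  f$name)
    }
    if (!is.null(rogue) &&
        !all(c("day", "replicate", "n_cells") %in% names(rogue)))
        stopf("rogue needs fields day, replicate, n_cells")
    structure(list(n_genes = as.integer(n_genes), families = families,
                   timepoints = as.integer(timepoints),
                   replicates_per_timepoint = as.integer(replicates_per_timepoint),
                   cells_per_replicate = as.integer(cells_per_replicate),
                   composition = comp, depth_mean = depth_mean,
                   depth_dispersion = depth_dispersion,
                   nb_dispersion = nb_dispersion,
                   batch_effect_sd = batch_effect_sd,
                   mito_fraction_range = mito_fraction_range,
                   n_mito = as.integer(n_mito), exact = isTRUE(exact),
                   rogue = rogue,
                   allow_shared_markers = isTRUE(allow_shared_markers),
                   seed = as.integer(seed)),
              class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
    cat(sprintf("SimConfig: %d genes, %d families, days %s, %d replicates x %d cells, seed %d\n",
        x$n_genes, length(x$families),
        paste(x$timepoints, collapse = "/"),
        x$replicates_per_timepoint, x$cells_per_replicate, x$seed))
    invisible(x)
}

# assemble the gene universe: mitochondrial genes first, then the special
# (marker / program / Vegfa) genes, then numbered filler genes
.geneUniverse <- function(config) {
    special <- unique(c(unlist(lapply(config$families, `[[`, "markers")),
                        unlist(.subtypePrograms), "Vegfa"))
    mito <- sprintf("mt-%d", seq_len(config$n_mito))
    n_fill <- config$n_genes - length(mito) - length(special)
    if (n_fill < 0)
        stopf("n_genes too small: need at least %d genes",
              length(mito) + length(special))
    c(mito, special, sprintf("gene%04d", seq_len(n_fill)))
}

#' Simulate a labelled timecourse of single-cell count matrices
#'
#' Generates one genes x cells UMI count matrix per (timepoint, replicate)
#' unit under the configured model: per-gene log-normal baseline expression,
#' family markers elevated by their generative fold, subtype marker programs
#' and Vegfa dynamics within the mesenchymal family, a per-replicate
#' log-normal multiplicative batch factor, per-cell log-normal depth, a
#' designated mitochondrial gene block occupying a configured fraction of
#' each cell's UMIs, and negative-binomial count noise. Ground-truth labels
#' for every cell and gene are returned alongside.
#'
#' @param config a [simConfig()].
#' @return list with elements:
#'   \describe{
#'     \item{matrices}{named list of
#'       [SingleCellExperiment::SingleCellExperiment] objects, one per unit,
#'       with assay `counts` (sparse), colData `barcode`, `day`,
#'       `replicate`, `family`, `subtype`, and rowData `mito`, `marker_of`,
#'       `fold`.}
#'     \item{cell_truth}{DataFrame of per-cell ground truth over all units.}
#'     \item{gene_truth}{DataFrame of per-gene generative parameters.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulateTimecourse(simConfig(cells_per_replicate = 50, seed = 1))
#' names(sim$matrices)
#' @export
simulateTimecourse <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    withSeed(config$seed, .simulateTimecourseImpl(config))
}

.simulateTimecourseImpl <- function(config) {
    genes <- .geneUniverse(config)
    G <- length(genes)
    mito <- startsWith(genes, "mt-")
    fams <- config$families
    fam_names <- names(fams)

    # fixed per-simulation baseline relative expression; program genes and
    # Vegfa have zero baseline so subtype negativity is crisp
    lambda <- stats::setNames(stats::rlnorm(G, 0, 1), genes)
    prog_genes <- unique(c(unlist(.subtypePrograms), "Vegfa"))
    lambda[prog_genes] <- 0
    lambda[mito] <- 0          # mito block handled by per-cell fraction

    marker_of <- rep(NA_character_, G)
    fold_of <- rep(1, G)
    names(marker_of) <- names(fold_of) <- genes
    for (f in fams) {
        marker_of[f$markers][is.na(marker_of[f$markers])] <- f$name
        fold_of[f$markers] <- pmax(fold_of[f$markers], f$marker_fold)
    }

    # rogue profile: baseline permuted over the non-mito, non-program genes
    rogue_lambda <- NULL
    if (!is.null(config$rogue)) {
        perm_idx <- which(!mito)
        rogue_lambda <- lambda
        rogue_lambda[perm_idx] <- lambda[sample(perm_idx)]
    }

    sub_spec <- NULL
    sub_family <- NA_character_
    for (f in fams) if (!is.null(f$subtypes)) {
        sub_spec <- f$subtypes; sub_family <- f$name
    }

    matrices <- list()
    truth <- list()
    for (day in config$timepoints) {
        dchr <- as.character(day)
        for (r in seq_len(config$replicates_per_timepoint)) {
            rep_id <- sprintf("r%d", r)
            uid <- unitId(day, rep_id)
            n <- config$cells_per_replicate
            batch <- if (config$batch_effect_sd > 0)
                exp(stats::rnorm(G, 0, config$batch_effect_sd)) else rep(1, G)

            fam_idx <- sample(length(fams), n, replace = TRUE,
                              prob = config$composition[, dchr])
            cell_family <- fam_names[fam_idx]
            cell_subtype <- rep(NA_character_, n)
            if (!is.null(sub_spec)) {
                in_sub <- cell_family == sub_family
                if (any(in_sub)) {
                    w <- sub_spec$weights[, dchr]
                    cell_subtype[in_sub] <- sample(rownames(sub_spec$weights),
                        sum(in_sub), replace = TRUE, prob = w)
                }
            }

            # per-family expected relative expression (with batch factor)
            famW <- matrix(rep(lambda * batch, length(fams)),
                           nrow = length(fams), byrow = TRUE,
                           dimnames = list(fam_names, genes))
            for (f in fams)
                famW[f$name, f$markers] <- famW[f$name, f$markers] * f$marker_fold

            W <- famW[fam_idx, , drop = FALSE]
            if (!is.null(sub_spec)) {
                lev <- sub_spec$program_level
                for (st in names(sub_spec$programs)) {
                    rows <- which(!is.na(cell_subtype) & cell_subtype == st)
                    if (!length(rows)) next
                    pg <- sub_spec$programs[[st]]
                    W[rows, pg] <- W[rows, pg] + lev * rep(batch[match(pg, genes)],
                                                           each = length(rows))
                    W[rows, "Vegfa"] <- sub_spec$vegfa[st, dchr] *
                        batch[match("Vegfa", genes)]
                }
            }

            is_rogue <- !is.null(config$rogue) &&
                config$rogue$day == day && config$rogue$replicate == rep_id
            if (is_rogue) {
                nr <- config$rogue$n_cells
                Wr <- matrix(rep(rogue_lambda * batch, nr), nrow = nr,
                             byrow = TRUE, dimnames = list(NULL, genes))
                W <- rbind(W, Wr)
                cell_family <- c(cell_family, rep("rogue", nr))
                cell_subtype <- c(cell_subtype, rep(NA_character_, nr))
                n <- n + nr
            }

            depth <- if (config$exact) rep(config$depth_mean, n)
                     else stats::rlnorm(n, log(config$depth_mean),
                                        config$depth_dispersion)
            mito_frac <- if (config$exact)
                rep(mean(config$mito_fraction_range), n)
            else stats::runif(n, config$mito_fraction_range[1],
                              config$mito_fraction_range[2])

            rs <- rowSums(W[, !mito, drop = FALSE])
            mu <- W
            mu[, !mito] <- W[, !mito, drop = FALSE] *
                (depth * (1 - mito_frac) / rs)
            mu[, mito] <- depth * mito_frac / sum(mito)

            counts <- if (config$exact) round(mu)
                else if (config$nb_dispersion == 0)
                    matrix(stats::rpois(length(mu), as.vector(mu)), nrow = n)
                else matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                        size = 1 / config$nb_dispersion), nrow = n)

            barcodes <- sprintf("cell%04d-%s", seq_len(n), uid)
            cd <- DataFrame(barcode = barcodes, day = day,
                            replicate = rep_id, family = cell_family,
                            subtype = cell_subtype, row.names = barcodes)
            rd <- DataFrame(gene = genes, mito = mito,
                            marker_of = marker_of, fold = fold_of,
                            row.names = genes)
            cts <- Matrix::Matrix(t(counts), sparse = TRUE,
                                  dimnames = list(genes, barcodes))
            sce <- SingleCellExperiment::SingleCellExperiment(
                assays = list(counts = cts), colData = cd, rowData = rd)
            S4Vectors::metadata(sce)$unit <- uid
            matrices[[uid]] <- sce
            truth[[uid]] <- DataFrame(barcode = barcodes, unit = uid,
                                      day = day, replicate = rep_id,
                                      family = cell_family,
                                      subtype = cell_subtype)
        }
    }
    gene_truth <- DataFrame(gene = genes, mito = mito, marker_of = marker_of,
                            fold = fold_of, row.names = genes)
    list(matrices = matrices, cell_truth = do.call(rbind, unname(truth)),
         gene_truth = gene_truth, config = config)
}

#' Write / read a SimConfig as structured text
#'
#' Serializes the scalar parameters, composition, family marker lists and
#' subtype blocks to YAML so a simulation is reproducible from a text file.
#'
#' @param config a [simConfig()].
#' @param path file path.
#' @return `readSimConfig` returns the reconstructed `SimConfig`.
#' @export
writeSimConfig <- function(config, path) {
    stopifnot(inherits(config, "SimConfig"))
    fam <- lapply(config$families, function(f) {
        out <- list(name = f$name, markers = f$markers,
                    marker_fold = f$marker_fold)
        if (!is.null(f$subtypes)) {
            s <- f$subtypes
            out$subtypes <- list(
                programs = s$programs,
                weights = apply(s$weights, 1, as.list, simplify = FALSE),
                vegfa = apply(s$vegfa, 1, as.list, simplify = FALSE),
                days = colnames(s$weights),
                program_level = s$program_level)
        }
        out
    })
    obj <- list(
        n_genes = config$n_genes, timepoints = config$timepoints,
        replicates_per_timepoint = config$replicates_per_timepoint,
        cells_per_replicate = config$cells_per_replicate,
        composition = apply(config$composition, 1, as.list, simplify = FALSE),
        composition_days = colnames(config$composition),
        depth_mean = config$depth_mean,
        depth_dispersion = config$depth_dispersion,
        nb_dispersion = config$nb_dispersion,
        batch_effect_sd = config$batch_effect_sd,
        mito_fraction_range = config$mito_fraction_range,
        n_mito = config$n_mito, exact = config$exact,
        allow_shared_markers = config$allow_shared_markers,
        seed = config$seed, families = fam)
    yaml::write_yaml(obj, path)
    invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
    obj <- yaml::read_yaml(path)
    rebuild_mat <- function(lst, days) {
        m <- do.call(rbind, lapply(lst, function(row) unlist(row)))
        rownames(m) <- names(lst); colnames(m) <- days
        m
    }
    fams <- lapply(obj$families, function(f) {
        st <- NULL
        if (!is.null(f$subtypes)) {
            s <- f$subtypes
            st <- list(programs = lapply(s$programs, unlist),
                       weights = rebuild_mat(s$weights, s$days),
                       vegfa = rebuild_mat(s$vegfa, s$days),
                       program_level = s$program_level)
        }
        familySpec(f$name, unlist(f$markers), f$marker_fold, subtypes = st)
    })
    names(fams) <- vapply(fams, `[[`, "", "name")
    simConfig(n_genes = obj$n_genes, families = fams,
              timepoints = unlist(obj$timepoints),
              replicates_per_timepoint = obj$replicates_per_timepoint,
              cells_per_replicate = obj$cells_per_replicate,
              composition = rebuild_mat(obj$composition, obj$composition_days),
              depth_mean = obj$depth_mean,
              depth_dispersion = obj$depth_dispersion,
              nb_dispersion = obj$nb_dispersion,
              batch_effect_sd = obj$batch_effect_sd,
              mito_fraction_range = unlist(obj$mito_fraction_range),
              n_mito = obj$n_mito, exact = obj$exact,
              allow_shared_markers = obj$allow_shared_markers,
              seed = obj$seed)
}
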