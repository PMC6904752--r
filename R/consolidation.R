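#' Provisional unsupervised clustering of one embedded replicate
#'
#' Two interchangeable backends: k-means with a fixed `k` (default), or
#' graph community detection (Louvain on a shared-nearest-neighbour graph)
#' at a `resolution` parameter. Both are deterministic given `seed`.
#' Cluster labels are integers contiguous from 0.
#'
#' @param embedding result of [embedPCA()] (or any cells x dims matrix).
#' @param k number of clusters (k-means backend).
#' @param method `"kmeans"` or `"graph"`.
#' @param resolution Louvain resolution (graph backend).
#' @param snn_k neighbours for the SNN graph (graph backend).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return list with `labels` (integer vector, named by cell), `method`,
#'   `k`, `seed`.
#' @export
clusterCells <- function(embedding, k = 7L, method = c("kmeans", "graph"),
                         resolution = 1, snn_k = 10L, seed = 0L,
                         nstart = 10L) {
    method <- match.arg(method)
    coords <- if (is.list(embedding)) embedding$coordinates else embedding
    n <- nrow(coords)
    labels <- withSeed(seed, {
        if (method == "kmeans") {
            if (k > n) stopf("more clusters requested (%d) than cells (%d)", k, n)
            km <- stats::kmeans(coords, centers = k, nstart = nstart,
                                iter.max = 100L)
            km$cluster - 1L
        } else {
            snn_k <- min(snn_k, n - 1L)
            d <- as.matrix(stats::dist(coords))
            nn <- apply(d, 1, function(row) order(row)[2:(snn_k + 1L)])
            nn <- t(nn)                     # cells x snn_k neighbour indices
            edges <- list(); w <- list()
            for (i in seq_len(n)) {
                for (j in nn[i, ]) {
                    if (j > i || !(i %in% nn[j, ])) {
                        shared <- length(intersect(nn[i, ], nn[j, ]))
                        jac <- shared / (2L * snn_k - shared)
                        if (jac > 0) {
                            edges[[length(edges) + 1L]] <- c(i, j)
                            w[[length(w) + 1L]] <- jac
                        }
                    }
                }
            }
            g <- igraph::graph_from_edgelist(do.call(rbind, edges),
                                             directed = FALSE)
            g <- igraph::simplify(igraph::add_vertices(
                g, max(0L, n - igraph::vcount(g))),
                edge.attr.comb = "first")
            comm <- igraph::cluster_louvain(g, weights = unlist(w),
                                            resolution = resolution)
            as.integer(igraph::membership(comm)) - 1L
        }
    })
    # relabel contiguously from 0 in order of first appearance size rank
    tab <- sort(table(labels), decreasing = TRUE)
    relab <- stats::setNames(seq_along(tab) - 1L, names(tab))
    labels <- unname(relab[as.character(labels)])
    names(labels) <- rownames(coords)
    list(labels = labels, method = method,
         k = length(unique(labels)), seed = seed)
}

#' Compute cluster centroids over a shared gene set
#'
#' @param logcounts genes x cells matrix of log-normalized values.
#' @param labels integer cluster labels per cell (0-based).
#' @param genes gene set (and order) for the centroid rows; must be shared
#'   by every CentroidSet that will be compared.
#' @param unit,day,replicate metadata recorded on the result.
#' @return a [CentroidSet-class].
#' @export
computeCentroids <- function(logcounts, labels, genes = rownames(logcounts),
                             unit = "unit", day = 0L, replicate = "r1") {
    if (!all(genes %in% rownames(logcounts)))
        stopf("centroid gene set absent from the matrix")
    x <- logcounts[genes, , drop = FALSE]
    labs <- sort(unique(labels))
    means <- t(vapply(labs, function(l)
        rowMeans(x[, labels == l, drop = FALSE]), numeric(length(genes))))
    dimnames(means) <- list(as.character(labs), genes)
    newCentroidSet(means, sizes = as.integer(table(factor(labels, labs))),
                   unit = unit, day = day, replicate = replicate)
}

#' Spearman rank correlation between two centroid sets
#'
#' `rho[i, j]` is the Spearman correlation (average-rank ties) between
#' centroid `i` of `a` and centroid `j` of `b` over their shared,
#' identically ordered gene set. A centroid with zero variance has no
#' defined rank correlation; its entries are `NA` with a warning.
#'
#' @param a,b [CentroidSet-class] objects over the same gene set.
#' @return a [CorrelationMap-class] (matching not yet computed).
#' @export
centroidRankCorrelation <- function(a, b) {
    ga <- colnames(centroidMeans(a)); gb <- colnames(centroidMeans(b))
    if (!identical(ga, gb))
        stopf("centroid sets must share an identically ordered gene set")
    ma <- centroidMeans(a); mb <- centroidMeans(b)
    const_a <- apply(ma, 1, function(r) diff(range(r)) == 0)
    const_b <- apply(mb, 1, function(r) diff(range(r)) == 0)
    if (any(const_a) || any(const_b))
        warnf("zero-variance centroid: correlations reported as NA")
    rho <- suppressWarnings(
        stats::cor(t(ma), t(mb), method = "spearman"))
    rho[const_a, ] <- NA_real_
    rho[, const_b] <- NA_real_
    dimnames(rho) <- list(rownames(ma), rownames(mb))
    new("CorrelationMap", rho = rho, unitA = a@unit, unitB = b@unit,
        dayA = a@day, dayB = b@day,
        matching = data.frame(a = character(), b = character(),
                              rho = numeric()),
        unmatchedA = character(), unmatchedB = character())
}

# reciprocal-best matching of one CorrelationMap at a correlation floor
.reciprocalMatch <- function(rho, min_rho) {
    pairs <- data.frame(a = character(), b = character(), rho = numeric())
    if (!nrow(rho) || !ncol(rho)) return(pairs)
    for (i in seq_len(nrow(rho))) {
        row <- rho[i, ]
        if (all(is.na(row))) next
        j <- which.max(row)
        col <- rho[, j]
        if (all(is.na(col))) next
        if (which.max(col) == i && !is.na(rho[i, j]) &&
            rho[i, j] >= min_rho)
            pairs <- rbind(pairs, data.frame(a = rownames(rho)[i],
                                             b = colnames(rho)[j],
                                             rho = rho[i, j]))
    }
    pairs
}

# exact optimal one-to-one assignment by exhaustive permutation search;
# sensitivity-analysis backend for small maps
.assignmentMatch <- function(rho, min_rho) {
    nr <- nrow(rho); nc <- ncol(rho)
    if (min(nr, nc) > 9L)
        stopf("assignment backend supports at most 9 clusters per side")
    swap <- nr > nc
    m <- if (swap) t(rho) else rho
    m[is.na(m)] <- -2          # below any real correlation
    small <- nrow(m); large <- ncol(m)
    perms <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
        out
    }
    combs <- utils::combn(large, small, simplify = FALSE)
    best <- NULL; best_val <- -Inf
    for (cols in combs) for (p in perms(cols)) {
        val <- sum(m[cbind(seq_len(small), p)])
        if (val > best_val) { best_val <- val; best <- p }
    }
    pairs <- data.frame(a = rownames(m), b = colnames(m)[best],
                        rho = m[cbind(seq_len(small), best)])
    if (swap) pairs <- data.frame(a = pairs$b, b = pairs$a, rho = pairs$rho)
    pairs[pairs$rho >= min_rho, , drop = FALSE]
}

#' Match clusters across correlation maps and flag discards
#'
#' For every map, clusters are paired by reciprocal best correlation (`i`
#' is `j`'s argmax and vice versa) subject to `rho >= min_rho`. A
#' provisional cluster is then discarded when it fails to obtain a
#' reciprocal match in at least `discard_fraction` of its within-timepoint
#' comparisons (default: all of them). Between-timepoint maps contribute
#' matches for consolidation but do not drive the discard rule.
#'
#' @param maps list of [CorrelationMap-class] objects covering the
#'   replicate pairs to compare.
#' @param min_rho minimum correlation for a valid match (default 0.5).
#' @param discard_fraction fraction of within-timepoint comparisons a
#'   cluster must be matched in to be retained (default 1 = all).
#' @param method `"reciprocal"` (default) or `"assignment"` (exact optimal
#'   one-to-one assignment; sensitivity backend, maps up to 9 x 9).
#' @return list with `maps` (matchings filled in), `discard` (data.frame
#'   unit/cluster/day/n_matched/n_comparisons/discarded) and `min_rho`.
#' @export
matchAndDiscard <- function(maps, min_rho = 0.5, discard_fraction = 1,
                            method = c("reciprocal", "assignment")) {
    if (!length(maps)) stopf("empty map list")
    method <- match.arg(method)
    clusters <- list()   # unit -> character vector of cluster labels
    days <- list()
    for (m in maps) {
        clusters[[m@unitA]] <- union(clusters[[m@unitA]], rownames(m@rho))
        clusters[[m@unitB]] <- union(clusters[[m@unitB]], colnames(m@rho))
        days[[m@unitA]] <- m@dayA; days[[m@unitB]] <- m@dayB
    }
    matched <- list(); compared <- list()
    for (u in names(clusters)) {
        matched[[u]] <- stats::setNames(integer(length(clusters[[u]])),
                                        clusters[[u]])
        compared[[u]] <- matched[[u]]
    }
    for (idx in seq_along(maps)) {
        m <- maps[[idx]]
        pairs <- if (method == "reciprocal")
            .reciprocalMatch(m@rho, min_rho)
        else .assignmentMatch(m@rho, min_rho)
        m@matching <- pairs
        m@unmatchedA <- setdiff(rownames(m@rho), pairs$a)
        m@unmatchedB <- setdiff(colnames(m@rho), pairs$b)
        maps[[idx]] <- m
        if (m@dayA == m@dayB) {      # within-timepoint: drives the discard rule
            compared[[m@unitA]] <- compared[[m@unitA]] + 1L
            compared[[m@unitB]] <- compared[[m@unitB]] + 1L
            matched[[m@unitA]][pairs$a] <- matched[[m@unitA]][pairs$a] + 1L
            matched[[m@unitB]][pairs$b] <- matched[[m@unitB]][pairs$b] + 1L
        }
    }
    rows <- list()
    for (u in names(clusters)) {
        nc <- compared[[u]]; nm <- matched[[u]]
        disc <- nc > 0 & nm < ceiling(discard_fraction * nc) - 1e-9
        rows[[u]] <- data.frame(unit = u, cluster = names(nm),
                                day = days[[u]], n_matched = unname(nm),
                                n_comparisons = unname(nc),
                                discarded = unname(disc))
    }
    list(maps = maps, discard = do.call(rbind, unname(rows)),
         min_rho = min_rho)
}

#' Consolidate matched provisional clusters into cell families
#'
#' Retained provisional clusters form the nodes of a graph whose edges are
#' the reciprocal matches across replicates and timepoints; families are
#' the connected components. A component that links two clusters of the
#' same unit is inconsistent: it is reported as a conflict and split by
#' repeatedly removing its weakest edge until consistent. Family labels
#' are assigned in decreasing order of total cell count ("A" largest).
#'
#' @param match_result output of [matchAndDiscard()].
#' @param sizes named list: per unit, a named integer vector of cells per
#'   cluster (names = cluster labels). Required for cell-count ordering;
#'   clusters missing from `sizes` count as size 1.
#' @param units optional data.frame with columns `unit`, `day`,
#'   `replicate` carried onto the output.
#' @return a [FamilyMap-class].
#' @export
consolidateFamilies <- function(match_result, sizes = NULL, units = NULL) {
    disc <- match_result$discard
    retained <- disc[!disc$discarded, , drop = FALSE]
    node_id <- function(unit, cluster) paste(unit, cluster, sep = "#")
    nodes <- node_id(retained$unit, retained$cluster)
    edges <- list(); weights <- numeric()
    for (m in match_result$maps) {
        p <- m@matching
        if (!nrow(p)) next
        na <- node_id(m@unitA, p$a); nb <- node_id(m@unitB, p$b)
        keep <- na %in% nodes & nb %in% nodes
        if (any(keep)) {
            edges[[length(edges) + 1L]] <- cbind(na[keep], nb[keep])
            weights <- c(weights, p$rho[keep])
        }
    }
    g <- igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(nodes)
    if (length(edges)) {
        el <- do.call(rbind, edges)
        g <- igraph::add_edges(g, t(el))
        igraph::E(g)$weight <- weights
    }
    unit_of <- sub("#.*$", "", nodes)
    conflicts <- character()
    repeat {
        comp <- igraph::components(g)
        memb <- unname(comp$membership[nodes])
        bad <- NULL
        for (ci in seq_len(comp$no)) {
            members <- which(memb == ci)
            if (anyDuplicated(unit_of[members])) { bad <- ci; break }
        }
        if (is.null(bad)) break
        conflicts <- union(conflicts,
            paste(sort(nodes[memb == bad]), collapse = ","))
        ee <- igraph::ends(g, igraph::E(g), names = FALSE)
        in_comp <- which(memb[ee[, 1]] == bad & memb[ee[, 2]] == bad)
        weakest <- in_comp[which.min(igraph::E(g)$weight[in_comp])]
        g <- igraph::delete_edges(g, weakest)
    }
    if (length(conflicts))
        warnf("inconsistent matching graph: %d component(s) split along weakest edges",
              length(conflicts))
    comp <- igraph::components(g)
    memb <- unname(comp$membership[nodes])
    size_of <- function(u, cl) {
        s <- sizes[[u]]
        if (is.null(s) || is.na(s[cl])) 1L else as.integer(s[cl])
    }
    n_cells <- as.integer(mapply(size_of, retained$unit, retained$cluster))
    comp_cells <- tapply(n_cells, memb, sum)
    ord <- order(-comp_cells, as.integer(names(comp_cells)))
    fam_label <- character(comp$no)
    lab <- c(LETTERS, paste0("A", LETTERS))
    fam_label[as.integer(names(comp_cells))[ord]] <- lab[seq_along(ord)]
    parse_unit <- function(u) {
        day <- as.integer(sub("^d(\\d+)\\..*$", "\\1", u))
        repl <- sub("^d\\d+\\.", "", u)
        list(day = day, replicate = repl)
    }
    pu <- lapply(retained$unit, parse_unit)
    assignments <- DataFrame(
        unit = retained$unit,
        day = vapply(pu, `[[`, numeric(1), "day"),
        replicate = vapply(pu, `[[`, character(1), "replicate"),
        cluster = retained$cluster,
        family = fam_label[memb],
        n_cells = n_cells)
    dd <- disc[disc$discarded, , drop = FALSE]
    pd <- lapply(dd$unit, parse_unit)
    discarded <- DataFrame(
        unit = dd$unit,
        day = if (nrow(dd)) vapply(pd, `[[`, numeric(1), "day") else numeric(),
        replicate = if (nrow(dd)) vapply(pd, `[[`, character(1), "replicate")
                    else character(),
        cluster = dd$cluster,
        n_cells = if (nrow(dd))
            as.integer(mapply(size_of, dd$unit, dd$cluster)) else integer())
    fm <- new("FamilyMap", assignments = assignments, discarded = discarded)
    S4Vectors::metadata(fm@assignments)$conflicts <- conflicts
    fm
}

#' Pool normalized matrices and correct the batch effect
#'
#' Pools cells over the intersection of the input gene sets and removes
#' the batch effect by per-gene batch-mean centering: within every batch,
#' each gene's mean is shifted to the pooled (global) gene mean. With a
#' single batch the corrected values equal the input values.
#'
#' @param matrices list of objects with a `logcounts` assay (or plain
#'   genes x cells matrices).
#' @param batch character vector: one batch label per matrix, or one per
#'   pooled cell.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assays
#'   `logcounts` and `corrected`, colData `batch` (plus any colData shared
#'   by the inputs).
#' @export
poolAndCorrect <- function(matrices, batch) {
    get_lc <- function(x) if (is.matrix(x)) x
        else SummarizedExperiment::assay(x, "logcounts")
    lcs <- lapply(matrices, get_lc)
    genes <- Reduce(intersect, lapply(lcs, rownames))
    if (!length(genes)) stopf("no shared genes across inputs")
    lcs <- lapply(lcs, function(m) m[genes, , drop = FALSE])
    ncells <- vapply(lcs, ncol, integer(1))
    if (length(batch) == length(matrices))
        batch <- rep(batch, times = ncells)
    pooled <- do.call(cbind, lcs)
    if (length(batch) != ncol(pooled))
        stopf("batch label vector length (%d) must match pooled cell count (%d)",
              length(batch), ncol(pooled))
    keep_batches <- names(which(table(batch) >= 2))
    if (length(keep_batches) < length(unique(batch))) {
        warnf("excluding batch(es) with fewer than 2 cells: %s",
              paste(setdiff(unique(batch), keep_batches), collapse = ", "))
        keep <- batch %in% keep_batches
        pooled <- pooled[, keep, drop = FALSE]
        batch <- batch[keep]
    }
    global_mean <- rowMeans(pooled)
    corrected <- pooled
    for (b in unique(batch)) {
        idx <- batch == b
        bm <- rowMeans(pooled[, idx, drop = FALSE])
        corrected[, idx] <- pooled[, idx, drop = FALSE] -
            bm + global_mean
    }
    cd <- DataFrame(batch = batch, row.names = colnames(pooled))
    cds <- lapply(matrices, function(x)
        if (is.matrix(x)) NULL else SummarizedExperiment::colData(x))
    if (!any(vapply(cds, is.null, logical(1)))) {
        shared <- Reduce(intersect, lapply(cds, colnames))
        if (length(shared)) {
            extra <- do.call(rbind, lapply(cds, function(d)
                d[, shared, drop = FALSE]))
            cd <- cbind(cd, extra[colnames(pooled), , drop = FALSE])
        }
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(logcounts = pooled, corrected = corrected),
        colData = cd)
}

#' Supplemental clustering of the merged, corrected set
#'
#' Clusters the batch-corrected merged matrix, assigns every final cluster
#' to the family contributing the plurality of its cells, and emits the
#' per-unit contribution table mirroring the per-replicate PCA check.
#'
#' @param merged output of [poolAndCorrect()] whose colData carries a
#'   `family` column (provisional family per cell) and a `unit` column.
#' @param k number of final clusters.
#' @param n_hvg,n_components,seed,method passed to [embedPCA()] /
#'   [clusterCells()].
#' @return list with `labels` (0-based final cluster per cell), `family`
#'   (final family per cell), `cluster_family` (named map final cluster ->
#'   family) and `contribution` (clusters x units cell counts).
#' @export
finalCluster <- function(merged, k = 7L, n_hvg = 2000L, n_components = 20L,
                         seed = 0L, method = "kmeans", nstart = 50L) {
    emb <- embedPCA(SummarizedExperiment::assay(merged, "corrected"),
                    n_hvg = n_hvg, n_components = n_components)
    cl <- clusterCells(emb, k = k, method = method, seed = seed,
                       nstart = nstart)
    labels <- cl$labels
    fam <- as.character(merged$family)
    cluster_family <- vapply(sort(unique(labels)), function(l) {
        tab <- sort(table(fam[labels == l]), decreasing = TRUE)
        names(tab)[1]
    }, character(1))
    names(cluster_family) <- as.character(sort(unique(labels)))
    unit <- as.character(merged$unit)
    contribution <- as.matrix(table(labels, unit))
    contribution <- matrix(as.integer(contribution),
                           nrow = nrow(contribution),
                           dimnames = dimnames(contribution))
    list(labels = labels,
         family = unname(cluster_family[as.character(labels)]),
         cluster_family = cluster_family, contribution = contribution)
}

#' Diagonal dominance of a matched correlation map
#'
#' The fraction of matched clusters whose matched-partner correlation is
#' the strict maximum of their row — the "red diagonal" statistic. Also
#' returns, per matched row, the maximum off-match correlation and the
#' cluster achieving it, which surfaces related-family signal.
#'
#' @param map a [CorrelationMap-class].
#' @param matching optional matching data.frame (columns `a`, `b`);
#'   defaults to the matching stored on the map.
#' @return list with `dominance` (fraction in [0, 1]), and `rows`: a
#'   data.frame (a, b, rho, off_max, off_which, dominant).
#' @export
diagonalDominance <- function(map, matching = NULL) {
    m <- if (is.null(matching)) matchedPairs(map) else matching
    if (is.null(m) || !nrow(m)) stopf("empty matching: dominance undefined")
    rho <- corMatrix(map)
    rows <- lapply(seq_len(nrow(m)), function(i) {
        a <- m$a[i]; b <- m$b[i]
        r <- rho[a, ]
        off <- r[setdiff(colnames(rho), b)]
        off_max <- if (length(off)) max(off, na.rm = TRUE) else -Inf
        off_which <- if (length(off))
            names(off)[which.max(off)] else NA_character_
        data.frame(a = a, b = b, rho = r[b], off_max = off_max,
                   off_which = off_which,
                   dominant = is.finite(r[b]) && r[b] > off_max)
    })
    rows <- do.call(rbind, rows)
    list(dominance = mean(rows$dominant), rows = rows)
}
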