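#' Simulate a flow-cytometry event table
#'
#' Draws events from configured populations (EPC, mature endothelium,
#' other live cells, plus a dead fraction) with per-population channel
#' intensity distributions for Tie2, CD31, CD133, CD34 and a viability
#' channel (log10-scale arbitrary units, normal per channel). Ground-truth
#' population labels are attached. Deterministic given `seed`.
#'
#' @param n_events total events.
#' @param population_fractions named vector with entries `EPC` and `endo`
#'   in [0, 1], summing to at most 1; the remainder are other live cells.
#' @param channel_params named list of per-population channel means/sds;
#'   see [defaultChannelParams()]. Each population entry is a list with
#'   `mean` and `sd` named vectors over the five channels.
#' @param dead_fraction fraction of events drawn as nonviable.
#' @param sample_id,group sample metadata recorded per event.
#' @param seed RNG seed.
#' @return data.frame (EventTable) with columns `Tie2`, `CD31`, `CD133`,
#'   `CD34`, `viability`, `sample`, `group`, `truth`.
#' @export
simulateCytometry <- function(n_events,
                              population_fractions = c(EPC = 0.02,
                                                       endo = 0.05),
                              channel_params = defaultChannelParams(),
                              dead_fraction = 0.1,
                              sample_id = "s1", group = "injured",
                              seed = 1L) {
    pf <- population_fractions
    if (any(pf < 0 | pf > 1)) stopf("fractions must lie in [0, 1]")
    if (sum(pf) > 1) stopf("population fractions sum above 1")
    withSeed(seed, {
        probs <- c(EPC = unname(pf["EPC"]), endo = unname(pf["endo"]))
        probs[is.na(probs)] <- 0
        probs <- probs * (1 - dead_fraction)
        probs <- c(probs, other = 1 - dead_fraction - sum(probs),
                   dead = dead_fraction)
        truth <- sample(names(probs), n_events, replace = TRUE,
                        prob = probs)
        channels <- c("Tie2", "CD31", "CD133", "CD34", "viability")
        out <- matrix(NA_real_, n_events, length(channels),
                      dimnames = list(NULL, channels))
        for (popn in unique(truth)) {
            idx <- truth == popn
            par <- channel_params[[popn]]
            if (is.null(par)) stopf("no channel params for '%s'", popn)
            for (ch in channels)
                out[idx, ch] <- stats::rnorm(sum(idx), par$mean[[ch]],
                                             par$sd[[ch]])
        }
        data.frame(out, sample = sample_id, group = group, truth = truth)
    })
}

#' Default per-population channel parameters
#'
#' Log10-scale intensities: negative channels around 1.5, positive around
#' 3.5, sd 0.3; viability (e.g. propidium iodide) low in live events and
#' high in dead ones.
#'
#' @return named list over populations `EPC`, `endo`, `other`, `dead`.
#' @export
defaultChannelParams <- function() {
    mk <- function(Tie2, CD31, CD133, CD34, viability)
        list(mean = c(Tie2 = Tie2, CD31 = CD31, CD133 = CD133,
                      CD34 = CD34, viability = viability),
             sd = c(Tie2 = 0.3, CD31 = 0.3, CD133 = 0.3, CD34 = 0.3,
                    viability = 0.3))
    list(EPC   = mk(1.5, 1.5, 3.5, 3.5, 1.5),
         endo  = mk(3.5, 3.5, 1.5, 1.5, 1.5),
         other = mk(1.5, 1.5, 1.5, 1.5, 1.5),
         dead  = mk(1.5, 1.5, 1.5, 1.5, 3.5))
}

#' Default hierarchical gate tree
#'
#' Viable events (viability below cutoff) are split on CD31/Tie2: the
#' double-negative branch refined for CD34+ CD133+ defines endothelial
#' progenitor cells (EPC); the double-positive branch refined for CD133-
#' CD34- defines mature endothelium. The two definitions are mutually
#' exclusive by construction (opposite CD31/Tie2 signs).
#'
#' @param cutoffs named per-channel positivity cutoffs.
#' @return a `GateTree` list.
#' @export
defaultGateTree <- function(cutoffs = c(Tie2 = 2.5, CD31 = 2.5,
                                        CD133 = 2.5, CD34 = 2.5,
                                        viability = 2.5)) {
    structure(list(cutoffs = cutoffs, viability_channel = "viability"),
              class = "GateTree")
}

#' Gate cytometry events through the EPC / endothelium tree
#'
#' @param events EventTable data.frame with the channel columns and a
#'   `sample` column.
#' @param tree a [defaultGateTree()].
#' @return list with `labels` (per-event: "EPC", "endothelium",
#'   "other_live" or "nonviable") and `counts` (per-sample data.frame with
#'   columns sample, viable, EPC, endothelium, other_live).
#' @export
gateEvents <- function(events, tree = defaultGateTree()) {
    need <- c(names(tree$cutoffs), "sample")
    missing <- setdiff(need, colnames(events))
    if (length(missing))
        stopf("missing channel column(s): %s", paste(missing, collapse = ", "))
    co <- tree$cutoffs
    viable <- events[[tree$viability_channel]] <= co[["viability"]]
    pos <- function(ch) events[[ch]] > co[[ch]]
    epc <- viable & !pos("CD31") & !pos("Tie2") & pos("CD34") & pos("CD133")
    endo <- viable & pos("CD31") & pos("Tie2") & !pos("CD133") & !pos("CD34")
    labels <- rep("other_live", nrow(events))
    labels[!viable] <- "nonviable"
    labels[epc] <- "EPC"
    labels[endo] <- "endothelium"
    counts <- do.call(rbind, lapply(split(labels, events$sample),
        function(l) data.frame(viable = sum(l != "nonviable"),
                               EPC = sum(l == "EPC"),
                               endothelium = sum(l == "endothelium"),
                               other_live = sum(l == "other_live"))))
    counts <- cbind(sample = rownames(counts), counts)
    rownames(counts) <- NULL
    list(labels = labels, counts = counts)
}

#' Compare gated population frequencies between two groups
#'
#' Frequencies are population counts normalized to total viable events per
#' sample. Reports group means and SDs, the fold change of group means
#' (`numerator` over `denominator` group), homoscedasticity checks by both
#' Levene's test (classic, centered on the mean) and the F-test, the
#' two-sided pooled-variance Student's t-test, and the Welch t-test as the
#' fallback indicated when the F-test rejects at 0.05.
#'
#' @param counts integer population count per sample.
#' @param totals integer viable-event total per sample.
#' @param groups group label per sample (exactly two levels).
#' @param numerator,denominator which group forms the fold-change ratio;
#'   default: first and second level of `groups`.
#' @return list (GroupComparison) with `frequencies`, `group_stats`,
#'   `fold_change`, `levene_p`, `f_test_p`, `t_pooled` (statistic, p),
#'   `t_welch` (statistic, p), `recommended` ("pooled" or "welch").
#' @export
compareGroups <- function(counts, totals, groups, numerator = NULL,
                          denominator = NULL) {
    if (any(totals <= 0)) stopf("a sample has zero viable events")
    groups <- as.character(groups)
    lev <- unique(groups)
    if (length(lev) != 2) stopf("exactly two groups required")
    if (any(table(groups) < 2)) stopf("at least 2 samples per group")
    if (is.null(numerator)) numerator <- lev[1]
    if (is.null(denominator)) denominator <- lev[2]
    freq <- counts / totals
    f1 <- freq[groups == numerator]
    f2 <- freq[groups == denominator]
    gs <- data.frame(group = c(numerator, denominator),
                     n = c(length(f1), length(f2)),
                     mean = c(mean(f1), mean(f2)),
                     sd = c(stats::sd(f1), stats::sd(f2)))
    lev_p <- tryCatch({
        d <- data.frame(freq = freq, g = factor(groups))
        car::leveneTest(freq ~ g, data = d, center = mean)[1, "Pr(>F)"]
    }, error = function(e) NA_real_)
    f_p <- tryCatch(stats::var.test(f1, f2)$p.value,
                    error = function(e) NA_real_)
    pooled <- stats::t.test(f1, f2, var.equal = TRUE)
    welch <- stats::t.test(f1, f2, var.equal = FALSE)
    list(frequencies = data.frame(sample = seq_along(freq),
                                  group = groups, frequency = freq),
         group_stats = gs,
         fold_change = mean(f1) / mean(f2),
         levene_p = lev_p, f_test_p = f_p,
         t_pooled = list(statistic = unname(pooled$statistic),
                         p = pooled$p.value),
         t_welch = list(statistic = unname(welch$statistic),
                        p = welch$p.value),
         recommended = if (!is.na(f_p) && f_p < 0.05) "welch" else "pooled")
}
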