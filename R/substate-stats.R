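# Per-cluster contact frequency statistics: frequency tables, contact
# variance across clusters, residue-level max-variance mapping, the
# recurrence index, and cross-referencing with mutational hotspot data.

.labelsVector <- function(labels) {
    if (is(labels, "InterfaceClustering")) labels@labels else
        as.integer(labels)
}

#' Relative contact frequencies per cluster
#'
#' For every contact observed at least once in the series and every
#' cluster, the proportion of the cluster's snapshots that exhibit the
#' contact. Contacts absent from a cluster get frequency 0.
#'
#' @param contact_series list of [ContactSet-class].
#' @param labels an [InterfaceClustering-class] or integer vector aligned
#'   with the series.
#' @return data.frame with columns `contact`, `chain1`, `resid1`, `chain2`,
#'   `resid2`, `cluster`, `frequency`.
#' @export
contactFrequencies <- function(contact_series, labels) {
    lab <- .labelsVector(labels)
    if (length(lab) != length(contact_series))
        stop("labels must align with the contact series", call. = FALSE)
    keys <- lapply(contact_series, contactKeys)
    universe <- sort(unique(unlist(keys)))
    if (length(universe) == 0L)
        stop("no contacts observed in the series", call. = FALSE)
    parts <- do.call(rbind, strsplit(universe, "[:|]"))
    clusters <- sort(unique(lab))
    rows <- lapply(clusters, function(cl) {
        idx <- which(lab == cl)
        inc <- vapply(keys[idx], function(k) universe %in% k,
                      logical(length(universe)))
        counts <- rowSums(matrix(inc, nrow = length(universe)))
        data.frame(contact = universe,
                   chain1 = parts[, 1], resid1 = as.integer(parts[, 2]),
                   chain2 = parts[, 3], resid2 = as.integer(parts[, 4]),
                   cluster = cl, frequency = counts / length(idx),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Variance of contact frequencies across clusters
#'
#' Population variance (divide by the number of clusters) of each contact's
#' per-cluster relative frequencies. With frequencies in [0, 1] the
#' variance is bounded by 0.25, attained by a contact always present in one
#' cluster and always absent in another (two clusters). Population rather
#' than sample variance keeps that bound and suits the small number of
#' clusters typical of interface substates.
#'
#' @param freq_table output of [contactFrequencies()].
#' @return data.frame `contact`, `chain1`, `resid1`, `chain2`, `resid2`,
#'   `variance`.
#' @export
contactVariance <- function(freq_table) {
    nc <- length(unique(freq_table$cluster))
    if (nc < 2)
        stop("variance across clusters needs at least 2 clusters",
             call. = FALSE)
    sp <- split(freq_table, freq_table$contact)
    rows <- lapply(sp, function(d) {
        f <- d$frequency
        data.frame(contact = d$contact[1], chain1 = d$chain1[1],
                   resid1 = d$resid1[1], chain2 = d$chain2[1],
                   resid2 = d$resid2[1],
                   variance = mean((f - mean(f))^2),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$contact), , drop = FALSE]
}

#' Map contact variances to residues
#'
#' Each residue receives the maximum variance over the contacts it
#' participates in: a residue seen with variance 0.1 against one partner
#' and 0.3 against another scores 0.3. Residues with no observed contact
#' are omitted.
#'
#' @param variances output of [contactVariance()].
#' @return data.frame `chain`, `resid`, `max_variance`.
#' @export
residueMaxVariance <- function(variances) {
    long <- rbind(
        data.frame(chain = variances$chain1, resid = variances$resid1,
                   v = variances$variance),
        data.frame(chain = variances$chain2, resid = variances$resid2,
                   v = variances$variance))
    agg <- stats::aggregate(v ~ chain + resid, data = long, FUN = max)
    out <- data.frame(chain = agg$chain, resid = agg$resid,
                      max_variance = agg$v, stringsAsFactors = FALSE)
    out[order(out$chain, out$resid), , drop = FALSE]
}

#' Recurrence index of interface residues
#'
#' For each residue: within every cluster, the best (maximum) relative
#' frequency over its contact partners; across clusters, the minimum of
#' those maxima. A residue engaged in a reliable contact in every substate
#' scores near 1; a residue whose contacts disappear in some substate
#' scores low (0 when it has no contact at all in a cluster, the maximum
#' over an empty partner set).
#'
#' @param freq_table output of [contactFrequencies()].
#' @return data.frame `chain`, `resid`, `recurrence`.
#' @examples
#' # residue A:1 in contact with B:1 at 100% and B:2 at 4% in cluster 1,
#' # and at 10% / B:3 at 60% in cluster 2 -> recurrence 0.6
#' ser <- list()
#' tab <- data.frame(
#'   contact = c("A:1|B:1", "A:1|B:2", "A:1|B:3"),
#'   chain1 = "A", resid1 = 1L, chain2 = "B", resid2 = c(1L, 2L, 3L))
#' tab <- rbind(transform(tab, cluster = 1,
#'                        frequency = c(1, 0.04, 0)),
#'              transform(tab, cluster = 2,
#'                        frequency = c(0.10, 0, 0.60)))
#' recurrenceIndex(tab)
#' @export
recurrenceIndex <- function(freq_table) {
    clusters <- sort(unique(freq_table$cluster))
    long <- rbind(
        data.frame(chain = freq_table$chain1, resid = freq_table$resid1,
                   cluster = freq_table$cluster, f = freq_table$frequency),
        data.frame(chain = freq_table$chain2, resid = freq_table$resid2,
                   cluster = freq_table$cluster, f = freq_table$frequency))
    inner <- stats::aggregate(f ~ chain + resid + cluster, data = long,
                              FUN = max)
    outer_min <- stats::aggregate(f ~ chain + resid, data = inner,
                                  FUN = min)
    out <- data.frame(chain = outer_min$chain, resid = outer_min$resid,
                      recurrence = outer_min$f, stringsAsFactors = FALSE)
    out[order(out$chain, out$resid), , drop = FALSE]
}

#' Combined per-residue substate scores
#'
#' Convenience wrapper joining [residueMaxVariance()] and
#' [recurrenceIndex()] into one table.
#'
#' @param freq_table output of [contactFrequencies()].
#' @return data.frame `chain`, `resid`, `max_variance`, `recurrence`.
#' @export
residueScores <- function(freq_table) {
    mv <- residueMaxVariance(contactVariance(freq_table))
    ri <- recurrenceIndex(freq_table)
    out <- merge(mv, ri, by = c("chain", "resid"), all = TRUE)
    out[order(out$chain, out$resid), , drop = FALSE]
}

#' Read a single-point mutation table
#'
#' Accepts a CSV with either explicit `chain` and `resid` columns, or a
#' SKEMPI-style `mutation` column of the form `KI31A` (wild-type residue,
#' chain, position, mutant). Records describing multiple simultaneous
#' mutations (comma-separated) are dropped. A `ddg` column (kcal/mol) is
#' required.
#'
#' @param path CSV file path.
#' @return data.frame `chain`, `resid`, `mutation`, `ddg`.
#' @export
readMutationTable <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(d) <- tolower(names(d))
    if (!"ddg" %in% names(d))
        stop("mutation table needs a 'ddg' column (kcal/mol)",
             call. = FALSE)
    if (all(c("chain", "resid") %in% names(d))) {
        if (is.null(d$mutation)) d$mutation <- NA_character_
    } else if ("mutation" %in% names(d)) {
        multi <- grepl(",", d$mutation)
        d <- d[!multi, , drop = FALSE]
        m <- regmatches(d$mutation,
                        regexec("^([A-Z])([A-Za-z0-9])([0-9]+)([A-Z])$",
                                d$mutation))
        bad <- vapply(m, length, integer(1)) == 0L
        if (any(bad))
            stop("unparseable mutation code(s): ",
                 paste(unique(d$mutation[bad]), collapse = ", "),
                 call. = FALSE)
        d$chain <- vapply(m, `[`, character(1), 3)
        d$resid <- as.integer(vapply(m, `[`, character(1), 4))
    } else {
        stop("mutation table needs 'chain'+'resid' or 'mutation' columns",
             call. = FALSE)
    }
    data.frame(chain = d$chain, resid = as.integer(d$resid),
               mutation = d$mutation, ddg = as.numeric(d$ddg),
               stringsAsFactors = FALSE)
}

#' Cross-reference residue scores with mutational hotspots
#'
#' Flags a residue as hotspot when any single mutation at that residue has
#' a binding free-energy change beyond the threshold. The default rule is
#' `ddg < -2.0` kcal/mol; `flip_sign = TRUE` applies `ddg > +2.0` for
#' datasets using the opposite (destabilising-positive) sign convention.
#' Mutated residues absent from the score table are reported as a warning,
#' not an error.
#'
#' @param scores data.frame from [residueScores()] (columns `chain`,
#'   `resid`).
#' @param mutations data.frame from [readMutationTable()].
#' @param threshold hotspot threshold in kcal/mol.
#' @param flip_sign flip the inequality for the opposite sign convention.
#' @return `scores` with a logical `hotspot` column added.
#' @export
hotspotCrossref <- function(scores, mutations, threshold = -2.0,
                            flip_sign = FALSE) {
    is_hot <- if (flip_sign) mutations$ddg > -threshold
              else mutations$ddg < threshold
    hot <- unique(paste(mutations$chain[is_hot], mutations$resid[is_hot]))
    skey <- paste(scores$chain, scores$resid)
    mkey <- unique(paste(mutations$chain, mutations$resid))
    unmatched <- setdiff(mkey, skey)
    if (length(unmatched))
        warning("mutated residue(s) not in score table: ",
                paste(unmatched, collapse = ", "), call. = FALSE)
    scores$hotspot <- skey %in% hot
    scores
}
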