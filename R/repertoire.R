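#' Per-branch expected change summary
#'
#' Aggregates an [branch_event_posteriors()] result into per-branch
#' expected counts of family gains (originations) `G`, losses
#' (extinctions) `X`, expansions `E` and contractions `K`, together with
#' the net repertoire change `G - X` and the net multicopy change
#' `E - K`. When an [ancestral_state_posteriors()] result is supplied
#' the expected repertoire sizes of parent and child are included so the
#' net change can be cross-checked against the repertoire delta.
#'
#' @param events an `event_posteriors` object.
#' @param ancestral optional `ancestral_states` object.
#' @param tree optional [species_tree] (required with `ancestral`).
#' @return data frame of class `branch_change_summary`.
#' @export
branch_change_summary <- function(events, ancestral = NULL, tree = NULL) {
  ex <- events$expected
  out <- data.frame(branch = rownames(ex),
                    gains = ex[, "origination"],
                    losses = ex[, "extinction"],
                    expansions = ex[, "expansion"],
                    contractions = ex[, "contraction"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$net_families <- out$gains - out$losses
  out$net_multicopy <- out$expansions - out$contractions
  if (!is.null(ancestral)) {
    if (is.null(tree)) stopf("supply the tree to join ancestral repertoires")
    pres <- ancestral$expected[, "single"] + ancestral$expected[, "multi"]
    out$parent_repertoire <- pres[tree$edge_parent]
    out$child_repertoire <- pres[tree$edge_child]
  }
  class(out) <- c("branch_change_summary", "data.frame")
  out
}

#' Classify the evolutionary mode of one lineage
#'
#' Labels a branch by comparing its expected family gains `G`, losses
#' `X`, expansions `E` and contractions `K`:
#' \itemize{
#' \item \strong{Expansion}: gains at least twice the losses and
#'   expansions at least twice the contractions (`G >= 2X` and `E >= 2K`).
#' \item \strong{Streamlining}: losses at least twice the gains and
#'   expansions not exceeding contractions by more than 20\%
#'   (`X >= 2G` and `E <= 1.2K`).
#' \item \strong{Specialization}: losses at least twice the gains and
#'   expansions at least twice the contractions (`X >= 2G` and `E >= 2K`).
#' \item \strong{Remodeling}: absolute net change below 60\% of the
#'   total turnover and more expansions than contractions
#'   (`|G - X| < 0.6 (G + X)` and `E > K`).
#' }
#' Rules are tested in the order Expansion, Streamlining,
#' Specialization, Remodeling (the loss-dominated rules share a clause
#' and must be ordered); a branch matching none is `Unclassified`. All
#' rule terms are returned for audit.
#'
#' @param gains,losses,expansions,contractions expected event counts for
#'   one branch (scalars).
#' @return list with `label` and `terms` (named logical vector of every
#'   rule clause evaluated).
#' @export
classify_mode <- function(gains, losses, expansions, contractions) {
  G <- gains; X <- losses; E <- expansions; K <- contractions
  if (any(!is.finite(c(G, X, E, K))) || any(c(G, X, E, K) < 0)) {
    stopf("event expectations must be finite and non-negative")
  }
  terms <- c(
    expansion_gain_dominant = G >= 2 * X,
    expansion_sizes_up = E >= 2 * K,
    loss_dominant = X >= 2 * G,
    streamlining_sizes_flat = E <= 1.2 * K,
    specialization_sizes_up = E >= 2 * K,
    remodeling_low_net = abs(G - X) < 0.6 * (G + X),
    remodeling_sizes_up = E > K
  )
  label <- if (G + X == 0) {
    "Unclassified"
  } else if (terms[["expansion_gain_dominant"]] && terms[["expansion_sizes_up"]]) {
    "Expansion"
  } else if (terms[["loss_dominant"]] && terms[["streamlining_sizes_flat"]]) {
    "Streamlining"
  } else if (terms[["loss_dominant"]] && terms[["specialization_sizes_up"]]) {
    "Specialization"
  } else if (terms[["remodeling_low_net"]] && terms[["remodeling_sizes_up"]]) {
    "Remodeling"
  } else "Unclassified"
  list(label = label, terms = terms,
       note = if (G + X == 0) "no expected gains or losses" else NULL)
}

#' Classify evolutionary modes for every branch
#'
#' @param summary a [branch_change_summary()] data frame.
#' @param branches optional character vector restricting the branch set
#'   (e.g. to the ingroup lineages).
#' @return data frame: branch, the four expectations, mode label and the
#'   audit terms as logical columns.
#' @export
classify_modes <- function(summary, branches = NULL) {
  s <- summary
  if (!is.null(branches)) s <- s[s$branch %in% branches, , drop = FALSE]
  res <- lapply(seq_len(nrow(s)), function(i) {
    m <- classify_mode(s$gains[i], s$losses[i], s$expansions[i], s$contractions[i])
    c(list(branch = s$branch[i], mode = m$label), as.list(m$terms))
  })
  out <- do.call(rbind, lapply(res, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  merge(s[, c("branch", "gains", "losses", "expansions", "contractions")],
        out, by = "branch", sort = FALSE)
}

#' High-confidence family event calls
#'
#' A family sustains a high-confidence gain on a branch when the
#' difference between its gain (origination) and loss (extinction)
#' probabilities exceeds the threshold, and a high-confidence loss when
#' the difference is below minus the threshold (strict inequalities on
#' both sides). At most one call is made per family-branch pair.
#'
#' @param events an `event_posteriors` object.
#' @param threshold difference threshold in (0, 1] (default 0.6).
#' @return data frame: family, branch, type (`gain`/`loss`), score
#'   (gain probability minus loss probability).
#' @export
call_high_confidence_events <- function(events, threshold = 0.6) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  score <- events$prob[, , "origination"] - events$prob[, , "extinction"]
  idx <- which(abs(score) > threshold, arr.ind = TRUE)
  if (length(idx) == 0) {
    return(data.frame(family = character(0), branch = character(0),
                      type = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(family = dimnames(events$prob)[[1]][idx[, 1]],
             branch = dimnames(events$prob)[[2]][idx[, 2]],
             type = ifelse(score[idx] > 0, "gain", "loss"),
             score = score[idx],
             stringsAsFactors = FALSE)
}

#' Census of parallel gains and losses
#'
#' Families with at least two high-confidence gain calls are counted as
#' having parallel gains, and their calls totalled; same for losses.
#'
#' @param calls a [call_high_confidence_events()] data frame.
#' @return list with `gain_families`, `parallel_gains`, `loss_families`,
#'   `parallel_losses`, and a `per_family` breakdown table.
#' @export
parallel_event_census <- function(calls) {
  tab <- as.data.frame(table(family = calls$family, type = calls$type),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  gf <- tab[tab$type == "gain" & tab$Freq >= 2, , drop = FALSE]
  lf <- tab[tab$type == "loss" & tab$Freq >= 2, , drop = FALSE]
  list(gain_families = nrow(gf), parallel_gains = sum(gf$Freq),
       loss_families = nrow(lf), parallel_losses = sum(lf$Freq),
       per_family = tab[order(-tab$Freq), , drop = FALSE])
}
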