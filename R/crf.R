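# Linear-chain CRF layer: sequence scoring, exact log-partition via the
# forward recursion in log space, Viterbi decoding, and a tape-based
# negative log-likelihood for training. Transition matrices are
# (L+2) x (L+2): the label set plus virtual START (row L+1) and STOP
# (column L+2).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Score one label sequence under a linear-chain CRF
#'
#' Sum of per-token emission scores along `labels` plus transition scores,
#' including START -> first label and last label -> STOP.
#'
#' @param emissions `n x L` matrix of per-token label scores.
#' @param transitions `(L+2) x (L+2)` transition score matrix; row `L+1` is
#'   START, column `L+2` is STOP.
#' @param labels Integer vector of length `n` with values in `1..L`.
#' @return Scalar score.
#' @export
crf_sequence_score <- function(emissions, transitions, labels) {
  n <- nrow(emissions)
  L <- ncol(emissions)
  stopifnot(length(labels) == n, all(labels >= 1L), all(labels <= L))
  s <- sum(emissions[cbind(seq_len(n), labels)])
  s <- s + transitions[L + 1L, labels[1L]]
  if (n > 1L) {
    s <- s + sum(transitions[cbind(labels[-n], labels[-1L])])
  }
  s + transitions[labels[n], L + 2L]
}

#' Log-partition function of a linear-chain CRF
#'
#' The log of the sum over all `L^n` label sequences of the exponentiated
#' sequence score, computed exactly by the forward recursion in log space.
#'
#' @inheritParams crf_sequence_score
#' @return Scalar log-partition value.
#' @export
crf_log_partition <- function(emissions, transitions) {
  n <- nrow(emissions)
  L <- ncol(emissions)
  alpha <- emissions[1L, ] + transitions[L + 1L, seq_len(L)]
  if (n > 1L) {
    Tsub <- transitions[seq_len(L), seq_len(L), drop = FALSE]
    for (t in 2:n) {
      m <- Tsub + alpha # alpha recycled down columns: m[i,j] = alpha[i]+T[i,j]
      mx <- m[cbind(max.col(t(m), ties.method = "first"), seq_len(L))]
      alpha <- mx + log(colSums(exp(sweep(m, 2L, mx, "-")))) + emissions[t, ]
    }
  }
  logsumexp(alpha + transitions[seq_len(L), L + 2L])
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Returns an argmax label sequence and its score; ties are broken toward
#' the lowest label index at every backpointer, so decoding is
#' deterministic.
#'
#' @inheritParams crf_sequence_score
#' @param mask Optional `(L+2) x (L+2)` logical matrix; `FALSE` entries mark
#'   transitions that are structurally forbidden (scored `-Inf`).
#' @return List with integer vector `labels` and scalar `score`.
#' @export
viterbi_decode <- function(emissions, transitions, mask = NULL) {
  n <- nrow(emissions)
  L <- ncol(emissions)
  if (!is.null(mask)) transitions[!mask] <- -Inf
  delta <- emissions[1L, ] + transitions[L + 1L, seq_len(L)]
  back <- matrix(0L, n, L)
  if (n > 1L) {
    Tsub <- transitions[seq_len(L), seq_len(L), drop = FALSE]
    for (t in 2:n) {
      m <- Tsub + delta # m[i,j]: from i to j
      arg <- apply(m, 2L, which.max) # first max = lowest previous label
      delta <- m[cbind(arg, seq_len(L))] + emissions[t, ]
      back[t, ] <- arg
    }
  }
  fin <- delta + transitions[seq_len(L), L + 2L]
  last <- which.max(fin)
  labels <- integer(n)
  labels[n] <- last
  if (n > 1L) {
    for (t in n:2) labels[t - 1L] <- back[t, labels[t]]
  }
  list(labels = labels, score = fin[last])
}

#' Mean CRF negative log-likelihood of a batch
#'
#' `mean(log Z - score(gold))` over sentences; non-negative, and zero only
#' when each gold path carries all probability mass.
#'
#' @param emissions A matrix, or list of matrices, of per-token label
#'   scores.
#' @param transitions `(L+2) x (L+2)` transition matrix.
#' @param labels An integer vector, or list of vectors, of gold labels.
#' @return Scalar mean negative log-likelihood.
#' @export
crf_nll <- function(emissions, transitions, labels) {
  if (is.matrix(emissions)) emissions <- list(emissions)
  if (!is.list(labels)) labels <- list(labels)
  stopifnot(length(emissions) == length(labels))
  vals <- mapply(function(e, y) {
    crf_log_partition(e, transitions) - crf_sequence_score(e, transitions, y)
  }, emissions, labels)
  mean(vals)
}

## ---- tape-based training objective ---------------------------------------

# Log-partition as a single fused tape node. `e` is an n x L emissions
# node, `tr` the (L+2) x (L+2) transitions node. The backward pass is the
# classical forward-backward recursion: the gradient of log Z with respect
# to an emission score is the unary posterior marginal, and with respect to
# a transition score the summed pairwise posterior marginal.
crf_log_partition_node <- function(e, tr) {
  ev <- e$val
  tv <- tr$val
  n <- nrow(ev)
  L <- ncol(ev)
  Tsub <- tv[seq_len(L), seq_len(L), drop = FALSE]
  colLSE <- function(m) {
    mx <- m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
    mx + log(colSums(exp(m - rep(mx, each = nrow(m)))))
  }
  alpha <- matrix(0, n, L)
  alpha[1L, ] <- ev[1L, ] + tv[L + 1L, seq_len(L)]
  if (n > 1L) {
    for (t in 2:n) {
      alpha[t, ] <- colLSE(Tsub + alpha[t - 1L, ]) + ev[t, ]
    }
  }
  logZ <- logsumexp(alpha[n, ] + tv[seq_len(L), L + 2L])
  ad_node(matrix(logZ, 1L, 1L), back = function(nd) {
    g <- nd$grad[1L]
    beta <- matrix(0, n, L)
    beta[n, ] <- tv[seq_len(L), L + 2L]
    if (n > 1L) {
      for (t in (n - 1L):1L) {
        # beta[t,i] = LSE_j(T[i,j] + e[t+1,j] + beta[t+1,j])
        w <- ev[t + 1L, ] + beta[t + 1L, ]
        m <- Tsub + rep(w, each = L)
        mx <- apply(m, 1L, max)
        beta[t, ] <- mx + log(rowSums(exp(m - mx)))
      }
    }
    ge <- exp(alpha + beta - logZ) # unary marginals
    gt <- matrix(0, L + 2L, L + 2L)
    if (n > 1L) {
      for (t in 2:n) {
        pair <- exp(alpha[t - 1L, ] + Tsub +
                      rep(ev[t, ] + beta[t, ], each = L) - logZ)
        gt[seq_len(L), seq_len(L)] <- gt[seq_len(L), seq_len(L)] + pair
      }
    }
    gt[L + 1L, seq_len(L)] <- ge[1L, ]
    gt[seq_len(L), L + 2L] <- ge[n, ]
    ad_acc(e, g * ge)
    ad_acc(tr, g * gt)
  })
}

# Gold-path score as a tape node.
crf_sequence_score_node <- function(e, tr, labels) {
  n <- nrow(e$val)
  L <- ncol(e$val)
  em <- ad_pick(e, cbind(seq_len(n), labels))
  path <- rbind(
    c(L + 1L, labels[1L]),
    if (n > 1L) cbind(labels[-n], labels[-1L]),
    c(labels[n], L + 2L)
  )
  ad_add(em, ad_pick(tr, path))
}

# Negative log-likelihood node for one sentence: log Z - gold score (>= 0).
crf_nll_node <- function(e, tr, labels) {
  ad_sub(crf_log_partition_node(e, tr), crf_sequence_score_node(e, tr, labels))
}

# Structural BMES transition mask (optional hard constraint at decode time):
# M_t/E_t may only follow B_t/M_t of the same type; B/S/O may not be
# followed by M/E of a different run; START may not enter M/E; M may not
# precede STOP.
bmes_transition_mask <- function(labels = bmes_labels()) {
  L <- length(labels)
  tag <- substr(labels, 1L, 1L)
  typ <- sub("^[BMES]_", "", labels)
  typ[labels == "O"] <- ""
  ok <- matrix(TRUE, L + 2L, L + 2L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (tag[j] %in% c("M", "E")) {
        ok[i, j] <- tag[i] %in% c("B", "M") && typ[i] == typ[j]
      } else if (tag[i] %in% c("B", "M")) {
        ok[i, j] <- FALSE # an open run must continue with M/E of its type
      }
    }
  }
  for (j in seq_len(L)) ok[L + 1L, j] <- !(tag[j] %in% c("M", "E"))
  for (i in seq_len(L)) ok[i, L + 2L] <- !(tag[i] %in% c("B", "M"))
  ok
}
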