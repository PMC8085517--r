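uniform_background <- function() c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

check_background <- function(background) {
  if (is.null(background)) return(uniform_background())
  stopifnot(length(background) == 4L, all(background > 0))
  if (is.null(names(background))) names(background) <- DNA_BASES
  background <- background[DNA_BASES]
  background / sum(background)
}

windows_to_matrix <- function(windows) {
  if (inherits(windows, "splice_window")) windows <- list(windows)
  seqs <- vapply(windows, function(w) {
    if (inherits(w, "splice_window")) w$seq else toupper(as.character(w))
  }, character(1L))
  if (length(seqs) == 0L) stop("at least one training window is required")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("training windows have mixed lengths")
  for (s in seqs) assert_dna(s, "training window", allow_n = FALSE)
  do.call(rbind, lapply(seqs, seq_chars))
}

#' Read fixed-length splice windows from a FASTA training set
#'
#' @param path FASTA file, one window per record.
#' @param kind Optional `"donor"`/`"acceptor"`; when given, lengths are
#'   checked against the window convention (9 / 23 nt).
#' @return Character vector of window sequences.
#' @export
windows_from_fasta <- function(path, kind = NULL) {
  x <- toupper(as.character(Biostrings::readDNAStringSet(path)))
  if (!is.null(kind)) {
    want <- window_length(match.arg(kind, c("donor", "acceptor")))
    if (any(nchar(x) != want)) {
      stop(sprintf("training windows must all be %d nt for kind '%s'",
                   want, kind))
    }
  }
  unname(x)
}

# --- position weight matrix -------------------------------------------------

#' Train a position-weight (PWM) splice-site model
#'
#' Per-position independent base probabilities with Laplace pseudocount:
#' `p[i][b] = (count + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param signal_windows Character vector (or list of [splice_window()]s)
#'   of aligned signal sequences, uniform length.
#' @param pseudocount Pseudocount added per base (default 1; 0 allowed for
#'   textbook examples).
#' @param background Base distribution used in scoring (default uniform).
#' @param kind Optional window kind label.
#' @return An object of class `wmm_model` with the probability matrix `p`
#'   (positions x bases) and `background`.
#' @export
train_wmm <- function(signal_windows, pseudocount = 1,
                      background = NULL, kind = NA_character_) {
  m <- windows_to_matrix(signal_windows)
  if (pseudocount == 0 && nrow(m) == 0L) stop("empty training set")
  n <- nrow(m); L <- ncol(m)
  p <- t(vapply(seq_len(L), function(i) {
    cnt <- table(factor(m[, i], levels = DNA_BASES))
    (as.numeric(cnt) + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4L)))
  colnames(p) <- DNA_BASES
  if (pseudocount == 0 && any(p == 0)) {
    # allowed, but scoring an unseen base then yields -Inf; keep as-is
  }
  stopifnot(all(abs(rowSums(p) - 1) < 1e-9))
  structure(list(kind = kind, L = L, p = p, n_train = n,
                 pseudocount = pseudocount,
                 background = check_background(background)),
            class = "wmm_model")
}

window_string <- function(window, L) {
  s <- if (inherits(window, "splice_window")) window$seq
       else toupper(as.character(window))
  assert_dna(s, "window", allow_n = FALSE)
  if (nchar(s) != L) {
    stop(sprintf("window length %d does not match model length %d",
                 nchar(s), L))
  }
  s
}

#' Score a window under a PWM model
#'
#' `sum_i log2(p[i][x_i] / q[x_i])`; positive scores mean the window looks
#' more like the signal than the background.
#'
#' @param model A `wmm_model` from [train_wmm()].
#' @param window Character or [splice_window()] of matching length.
#' @return log2-odds score.
#' @export
score_wmm <- function(model, window) {
  stopifnot(inherits(model, "wmm_model"))
  x <- seq_chars(window_string(window, model$L))
  idx <- match(x, DNA_BASES)
  sum(log2(model$p[cbind(seq_len(model$L), idx)] / model$background[idx]))
}

# --- inhomogeneous first-order Markov model ---------------------------------

#' Train a position-specific first-order Markov splice-site model
#'
#' Initial base distribution at position 1 plus a transition matrix at each
#' subsequent position, all Laplace-pseudocounted. Captures dependencies
#' between adjacent window positions only.
#'
#' @inheritParams train_wmm
#' @return An object of class `mm1_model` with `p1` (initial distribution)
#'   and `t` (list of 4x4 transition matrices for positions 2..L).
#' @export
train_mm1 <- function(signal_windows, pseudocount = 1,
                      kind = NA_character_) {
  m <- windows_to_matrix(signal_windows)
  L <- ncol(m); n <- nrow(m)
  if (L < 2L) stop("first-order model needs windows of length >= 2")
  cnt1 <- table(factor(m[, 1L], levels = DNA_BASES))
  p1 <- (as.numeric(cnt1) + pseudocount) / (n + 4 * pseudocount)
  names(p1) <- DNA_BASES
  trans <- lapply(2L:L, function(i) {
    t_i <- matrix(pseudocount, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
    tab <- table(factor(m[, i - 1L], levels = DNA_BASES),
                 factor(m[, i], levels = DNA_BASES))
    t_i <- t_i + as.matrix(tab)
    tot <- rowSums(t_i)
    t_i[tot == 0, ] <- 0.25  # unobserved context with pseudocount 0
    sweep(t_i, 1L, rowSums(t_i), "/")
  })
  for (t_i in trans) stopifnot(all(abs(rowSums(t_i) - 1) < 1e-9))
  structure(list(kind = kind, L = L, p1 = p1, t = trans, n_train = n,
                 pseudocount = pseudocount),
            class = "mm1_model")
}

#' Score a window under a first-order Markov model
#'
#' `log2( P(x1) * prod_i t[i][x_{i-1}][x_i] / prod_i q(x_i) )`.
#'
#' @param model An `mm1_model` from [train_mm1()].
#' @param window Character or [splice_window()] of matching length.
#' @param background Base distribution (default uniform).
#' @return log2-odds score.
#' @export
score_mm1 <- function(model, window, background = NULL) {
  stopifnot(inherits(model, "mm1_model"))
  q <- check_background(background)
  x <- seq_chars(window_string(window, model$L))
  idx <- match(x, DNA_BASES)
  logp <- log2(model$p1[idx[1L]])
  for (i in 2L:model$L) {
    logp <- logp + log2(model$t[[i - 1L]][idx[i - 1L], idx[i]])
  }
  unname(logp - sum(log2(q[idx])))
}

# Probability of one window under an mm1 model (used by tests/oracles).
prob_mm1 <- function(model, window) {
  x <- seq_chars(window_string(window, model$L))
  idx <- match(x, DNA_BASES)
  p <- model$p1[idx[1L]]
  for (i in 2L:model$L) p <- p * model$t[[i - 1L]][idx[i - 1L], idx[i]]
  unname(p)
}

# --- maximum entropy model --------------------------------------------------

# Enumerate all 4^L windows as an integer matrix of base indices
# (column j = window position j; column 1 varies fastest, so
# state_index(state_matrix(L)) == 1:4^L).
state_matrix <- function(L) {
  unname(as.matrix(expand.grid(rep(list(1:4), L))))
}

state_index <- function(states_sub) {
  # base-4 index (1-based) of each row of a (n x k) base-index matrix
  k <- ncol(states_sub)
  idx <- rep(1, nrow(states_sub))
  for (j in seq_len(k)) {
    idx <- idx + (states_sub[, j] - 1) * 4^(j - 1)
  }
  as.integer(idx)
}

empirical_marginal <- function(m, subset, pseudocount) {
  sub <- m[, subset, drop = FALSE]
  sub_idx <- state_index(matrix(match(sub, DNA_BASES), nrow = nrow(m)))
  k <- length(subset)
  cnt <- tabulate(sub_idx, nbins = 4^k)
  (cnt + pseudocount) / (nrow(m) + pseudocount * 4^k)
}

#' Fit a maximum-entropy splice-site model
#'
#' Finds the maximum-entropy distribution over all `4^L` windows whose
#' marginals on every constraint subset match the (pseudocounted) empirical
#' marginals of the training set, using cyclic iterative proportional
#' fitting (the Darroch-Ratcliff generalized iterative scaling family).
#' Captures dependencies between adjacent and non-adjacent positions,
#' depending on the subsets supplied. Exact fitting enumerates the full
#' state space and is limited to `L <= 9`.
#'
#' @param signal_windows Training windows (character vector), uniform
#'   length `L <= 9`.
#' @param constraint_subsets List of integer vectors of window positions;
#'   defaults to all unordered position pairs.
#' @param pseudocount Pseudocount used in the empirical marginals
#'   (default 1).
#' @param tolerance Convergence threshold on the maximum absolute marginal
#'   deviation (default 1e-6).
#' @param max_iter Maximum number of full sweeps (default 1000).
#' @param kind Optional window kind label.
#' @return An object of class `maxent_model` with the fitted probability
#'   vector `p` over all `4^L` states (lexicographic in position order,
#'   base order A,C,G,T), plus convergence diagnostics `max_dev` and
#'   `iterations`.
#' @export
fit_maxent <- function(signal_windows, constraint_subsets = NULL,
                       pseudocount = 1, tolerance = 1e-6,
                       max_iter = 1000L, kind = NA_character_) {
  m <- windows_to_matrix(signal_windows)
  L <- ncol(m)
  if (L > 9L) {
    stop("exact maximum-entropy fitting is limited to windows of length <= 9; supply an external factorized model for longer windows")
  }
  if (is.null(constraint_subsets)) {
    constraint_subsets <- if (L >= 2L) {
      unlist(lapply(seq_len(L - 1L), function(i) {
        lapply((i + 1L):L, function(j) c(i, j))
      }), recursive = FALSE)
    } else {
      list(1L)
    }
  }
  constraint_subsets <- lapply(constraint_subsets, as.integer)
  if (length(constraint_subsets) == 0L) {
    return(structure(list(kind = kind, L = L, subsets = list(),
                          targets = list(), p = rep(1 / 4^L, 4^L),
                          converged = TRUE, max_dev = 0,
                          iterations = 0L, pseudocount = pseudocount),
                     class = "maxent_model"))
  }
  for (s in constraint_subsets) {
    if (length(s) == 0L || any(s < 1L | s > L) || anyDuplicated(s)) {
      stop("constraint subset references invalid window positions")
    }
  }
  targets <- lapply(constraint_subsets, empirical_marginal, m = m,
                    pseudocount = pseudocount)
  S <- state_matrix(L)
  sub_idx <- lapply(constraint_subsets, function(s) {
    state_index(S[, s, drop = FALSE])
  })
  p <- rep(1 / 4^L, 4^L)
  it <- 0L; max_dev <- Inf
  while (it < max_iter) {
    it <- it + 1L
    for (ci in seq_along(constraint_subsets)) {
      cur <- as.numeric(rowsum(p, sub_idx[[ci]], reorder = TRUE))
      ratio <- ifelse(cur > 0, targets[[ci]] / cur, 0)
      p <- p * ratio[sub_idx[[ci]]]
    }
    p <- p / sum(p)
    max_dev <- max(vapply(seq_along(constraint_subsets), function(ci) {
      cur <- as.numeric(rowsum(p, sub_idx[[ci]], reorder = TRUE))
      max(abs(cur - targets[[ci]]))
    }, numeric(1L)))
    if (max_dev < tolerance) break
  }
  converged <- max_dev < tolerance
  if (!converged) {
    warning(sprintf("maximum-entropy fit did not converge: max marginal deviation %.3g after %d sweeps",
                    max_dev, it), call. = FALSE)
  }
  structure(list(kind = kind, L = L, subsets = constraint_subsets,
                 targets = targets, p = p, converged = converged,
                 max_dev = max_dev, iterations = it,
                 pseudocount = pseudocount),
            class = "maxent_model")
}

maxent_state_of <- function(model, window) {
  x <- seq_chars(window_string(window, model$L))
  state_index(matrix(match(x, DNA_BASES), nrow = 1L))
}

#' Score a window under a maximum-entropy model
#'
#' `log2( P_me(x) / P_background(x) )` with the background an independent
#' per-base distribution (default uniform).
#'
#' @param model A `maxent_model` from [fit_maxent()] or
#'   [load_maxent_score_table()].
#' @param window Character or [splice_window()] of matching length.
#' @param background Base distribution (default uniform).
#' @return log2-odds score.
#' @export
score_maxent <- function(model, window, background = NULL) {
  if (inherits(model, "maxent_score_table")) {
    return(lookup_maxent_table(model, window))
  }
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$p)) stop("maximum-entropy model is not fitted")
  q <- check_background(background)
  s <- window_string(window, model$L)
  idx <- match(seq_chars(s), DNA_BASES)
  log2(model$p[maxent_state_of(model, s)] / prod(q[idx]))
}

#' Load an externally published maximum-entropy score table
#'
#' Hook for long windows (e.g. 23-mer acceptors) or published donor tables
#' whose scores should be reproduced verbatim: a two-column tab-separated
#' file of window sequence and precomputed log2-odds score.
#'
#' @param path Tab-separated file with columns `seq` and `score`.
#' @param kind Window kind the table applies to.
#' @return An object of class `maxent_score_table`.
#' @export
load_maxent_score_table <- function(path, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c("character", "numeric"))
  if (!all(c("seq", "score") %in% names(df))) {
    stop("score table needs columns 'seq' and 'score'")
  }
  structure(list(kind = kind, seq = toupper(df$seq), score = df$score),
            class = "maxent_score_table")
}

lookup_maxent_table <- function(table, window) {
  s <- if (inherits(window, "splice_window")) window$seq
       else toupper(as.character(window))
  i <- match(s, table$seq)
  if (is.na(i)) stop(sprintf("window %s absent from the loaded score table", s))
  table$score[i]
}

# --- score panels -----------------------------------------------------------

#' Score a reference/mutant window pair under all available models
#'
#' Produces a tidy score panel: one row per metric with reference score,
#' mutant score and delta (mutant - reference). Implemented metrics are the
#' consensus value (`ss_percent`), PWM, first-order Markov and (where a
#' model is supplied and length-compatible) maximum entropy. External
#' scores -- e.g. a user-supplied deep-network gain score -- are passed
#' through untouched and labeled with their recall/precision band.
#'
#' @param reference_window,mutant_window [splice_window()]s of the same
#'   kind (mutant may be `NULL` for single-window panels).
#' @param models Named list with any of `wmm`, `mm1`, `maxent`.
#' @param background Base distribution used by the log-odds scores.
#' @param external_scores Named numeric vector of pass-through scores.
#' @param ss_matrix Optional frequency matrix for the consensus value.
#' @return A tibble of class `score_panel` with columns `metric`,
#'   `reference`, `mutant`, `delta`, `source`.
#' @export
score_panel <- function(reference_window, mutant_window = NULL,
                        models = list(), background = NULL,
                        external_scores = NULL, ss_matrix = NULL) {
  stopifnot(inherits(reference_window, "splice_window"))
  if (!is.null(mutant_window)) {
    stopifnot(inherits(mutant_window, "splice_window"))
    if (mutant_window$kind != reference_window$kind) {
      stop("reference and mutant windows have different kinds")
    }
  }
  score_both <- function(f) {
    r <- f(reference_window)
    m <- if (is.null(mutant_window)) NA_real_ else f(mutant_window)
    c(r, m)
  }
  rows <- list()
  sc <- score_both(function(w) ss_percent(w, frequency_matrix = ss_matrix))
  rows[["ss_percent"]] <- c(metric = "ss_percent", sc)
  if (!is.null(models$wmm)) {
    sc <- score_both(function(w) score_wmm(models$wmm, w))
    rows[["wmm_logodds"]] <- c(metric = "wmm_logodds", sc)
  }
  if (!is.null(models$mm1)) {
    sc <- score_both(function(w) score_mm1(models$mm1, w, background))
    rows[["mm1_logodds"]] <- c(metric = "mm1_logodds", sc)
  }
  if (!is.null(models$maxent)) {
    ok <- inherits(models$maxent, "maxent_score_table") ||
      (inherits(models$maxent, "maxent_model") &&
         models$maxent$L == nchar(reference_window$seq))
    if (ok) {
      sc <- score_both(function(w) score_maxent(models$maxent, w, background))
      rows[["maxent_logodds"]] <- c(metric = "maxent_logodds", sc)
    }
  }
  out <- tibble::tibble(
    metric = unname(vapply(rows, `[[`, character(1L), 1L)),
    reference = as.numeric(vapply(rows, `[[`, character(1L), 2L)),
    mutant = as.numeric(vapply(rows, `[[`, character(1L), 3L)),
    source = "computed"
  )
  if (!is.null(external_scores)) {
    ext <- tibble::tibble(
      metric = names(external_scores),
      reference = NA_real_,
      mutant = as.numeric(external_scores),
      source = paste0("external:", spliceai_band(as.numeric(external_scores)))
    )
    out <- rbind(out, ext)
  }
  out$delta <- ifelse(is.na(out$reference) | is.na(out$mutant),
                      NA_real_, out$mutant - out$reference)
  out <- out[, c("metric", "reference", "mutant", "delta", "source")]
  class(out) <- c("score_panel", class(out))
  out
}

#' Label a pass-through deep-network gain score by its threshold band
#'
#' Bands follow the conventional 0.2 / 0.5 / 0.8 cutoffs (high recall /
#' recommended / high precision). The score itself is never computed here,
#' only labeled.
#'
#' @param score Numeric vector of gain scores in `[0, 1]`.
#' @return Character vector of band labels.
#' @export
spliceai_band <- function(score) {
  cut(score, breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("below-high-recall", "high-recall", "recommended",
                 "high-precision"),
      right = FALSE) |> as.character()
}
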