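#' Construct a probabilistic context tree
#'
#' A context tree is a variable-length Markov chain source: a set of
#' suffix-free contexts (finite histories) each carrying a probability
#' distribution over the next symbol. The next symbol is drawn from the
#' distribution of the unique context that is a suffix of the past sequence.
#'
#' Symbols must be single characters; a context is written as the
#' concatenation of its symbols in time order (left = older), so `"12"` is
#' the history "1 then 2".
#'
#' @param contexts named list: names are context strings, values are numeric
#'   probability vectors aligned with `alphabet`.
#' @param alphabet character vector of single-character symbols. Defaults to
#'   the sorted set of characters appearing in the contexts.
#' @return An object of class `context_tree` with elements `alphabet`,
#'   `contexts` (character vector), `probs` (contexts x alphabet matrix) and
#'   `deterministic` (logical, one probability equal to 1).
#' @seealso [srt_tree()] for the packaged serial-reaction-time tree,
#'   [validate_tree()], [generate_sequence()].
#' @examples
#' tree <- context_tree(list("1" = c(0, 1, 0),
#'                           "12" = c(0, 0.26, 0.74),
#'                           "22" = c(1, 0, 0),
#'                           "3"  = c(1, 0, 0)),
#'                      alphabet = c("1", "2", "3"))
#' print(tree)
#' @export
context_tree <- function(contexts, alphabet = NULL) {
  if (!is.list(contexts) || is.null(names(contexts)) ||
      any(!nzchar(names(contexts)))) {
    stop("`contexts` must be a named list of probability vectors")
  }
  ctx <- names(contexts)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(ctx, ""))))
  }
  alphabet <- as.character(alphabet)
  if (length(alphabet) == 0L) stop("alphabet must be nonempty")
  if (any(nchar(alphabet) != 1L)) stop("symbols must be single characters")
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be unique")
  m <- length(alphabet)
  probs <- matrix(NA_real_, length(ctx), m,
                  dimnames = list(ctx, alphabet))
  for (i in seq_along(ctx)) {
    p <- as.numeric(contexts[[i]])
    if (length(p) != m) {
      stop(sprintf("context '%s': probability vector must have length %d",
                   ctx[i], m))
    }
    probs[i, ] <- p
  }
  structure(
    list(alphabet = alphabet,
         contexts = ctx,
         probs = probs,
         deterministic = apply(probs, 1L, function(p) any(p == 1))),
    class = "context_tree")
}

#' @export
print.context_tree <- function(x, ...) {
  cat("Context tree over alphabet {", paste(x$alphabet, collapse = ", "),
      "}\n", sep = "")
  for (i in seq_along(x$contexts)) {
    kind <- if (x$deterministic[i]) "fixed" else "variable"
    cat(sprintf("  context %-6s (%s): ", shQuote(x$contexts[i]), kind))
    cat(paste(sprintf("P(%s)=%g", x$alphabet, x$probs[i, ]), collapse = "  "),
        "\n")
  }
  invisible(x)
}

#' The packaged serial reaction time stimulus tree
#'
#' The three-symbol tree driving the SRT task: stimulus 1 is always followed
#' by 2; a 2 preceded by 1 is followed by 3 (74%) or another 2 (26%); a 2
#' preceded by 2, and a 3, are always followed by 1. Every realization
#' started at symbol 1 is a concatenation of the triplets (1,2,3) and
#' (1,2,2).
#'
#' @return a `context_tree`.
#' @export
srt_tree <- function() {
  context_tree(list("1"  = c(0, 1, 0),
                    "12" = c(0, 0.26, 0.74),
                    "22" = c(1, 0, 0),
                    "3"  = c(1, 0, 0)),
               alphabet = c("1", "2", "3"))
}

#' Validate a context tree
#'
#' Checks the structural invariants of a context tree and returns all
#' violations found (an empty character vector means the tree is valid):
#' probability vectors nonnegative and summing to 1 (tolerance 1e-12);
#' suffix-freeness (no context a proper suffix of another); completeness
#' (from every context, every positively-probable emission leads to a
#' history with a matching context).
#'
#' @param tree a `context_tree`.
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "context_tree"))
  bad <- character(0)
  ctx <- tree$contexts
  if (length(ctx) == 0L) return("context set is empty")
  if (anyDuplicated(ctx)) bad <- c(bad, "duplicate contexts")
  ctx_syms <- unique(unlist(strsplit(ctx, "")))
  extra <- setdiff(ctx_syms, tree$alphabet)
  if (length(extra)) {
    bad <- c(bad, sprintf("context symbol(s) outside alphabet: %s",
                          paste(extra, collapse = ", ")))
  }
  for (i in seq_along(ctx)) {
    p <- tree$probs[i, ]
    if (any(is.na(p)) || any(p < 0)) {
      bad <- c(bad, sprintf("context '%s': negative or missing probability",
                            ctx[i]))
    } else if (abs(sum(p) - 1) > 1e-12) {
      bad <- c(bad, sprintf(
        "context '%s': probabilities sum to %.15g, not 1", ctx[i], sum(p)))
    }
  }
  # suffix-freeness: no context is a proper suffix of another
  for (i in seq_along(ctx)) {
    for (j in seq_along(ctx)) {
      if (i != j && nchar(ctx[i]) < nchar(ctx[j]) &&
          endsWith(ctx[j], ctx[i])) {
        bad <- c(bad, sprintf(
          "contexts not suffix-free: '%s' is a suffix of '%s'",
          ctx[i], ctx[j]))
      }
    }
  }
  # completeness over reachable histories: context + positive emission must
  # again have a context suffix
  if (!length(bad)) {
    for (i in seq_along(ctx)) {
      for (a in tree$alphabet) {
        if (tree$probs[i, a] > 0 &&
            is.na(.match_one(tree, paste0(ctx[i], a)))) {
          bad <- c(bad, sprintf(
            "incomplete: history '%s%s' (reachable from context '%s') has no matching context",
            ctx[i], a, ctx[i]))
        }
      }
    }
  }
  bad
}

# longest matching suffix of a history string; NA if none
.match_one <- function(tree, history) {
  L <- min(nchar(history), max(nchar(tree$contexts)))
  if (L == 0L) return(NA_character_)
  nh <- nchar(history)
  for (l in L:1) {
    suf <- substr(history, nh - l + 1L, nh)
    if (suf %in% tree$contexts) return(suf)
  }
  NA_character_
}

#' Match the generating context of a history
#'
#' Returns the unique context of the tree that is a suffix of the given
#' history, or `NA` when no context matches (short leading histories).
#'
#' @param tree a `context_tree`.
#' @param history a character vector of symbols in time order, or a single
#'   string of concatenated symbols. May be empty.
#' @return the matched context string, or `NA_character_`.
#' @examples
#' match_context(srt_tree(), c("2", "1"))  # "1"
#' match_context(srt_tree(), "12")         # "12"
#' @export
match_context <- function(tree, history) {
  stopifnot(inherits(tree, "context_tree"))
  history <- .as_symbols(history)
  if (length(history) &&
      !all(history %in% tree$alphabet)) {
    stop("history contains symbols outside the alphabet")
  }
  .match_one(tree, paste(history, collapse = ""))
}

.as_symbols <- function(x) {
  x <- as.character(x)
  if (length(x) == 1L) x <- strsplit(x, "")[[1]]  # "" -> character(0)
  x
}

# per-position matched context for a full sequence: position t is matched
# against the history symbols[1..t-1]. Vectorized over positions: for each
# candidate suffix length l, suffix keys are built by prepending the l-lagged
# symbol vector; longer matches overwrite shorter ones (suffix-freeness makes
# at most one possible for a valid tree).
.match_seq <- function(tree, symbols) {
  n <- length(symbols)
  res <- rep(NA_character_, n)
  if (n == 0L) return(res)
  L <- max(nchar(tree$contexts))
  key <- rep("", n)
  for (l in seq_len(L)) {
    lag <- c(rep("", l), symbols[seq_len(n - l)])
    key <- paste0(lag, key)       # suffix of length l ending just before t
    valid <- seq_len(n) > l
    hit <- valid & key %in% tree$contexts
    res[hit] <- key[hit]
  }
  res
}

# context-indexed transition table: entry [i, a] is the index of the context
# matched after emitting symbol a from context i (NA when the emission has
# probability 0 or the tree is incomplete)
.context_transitions <- function(tree) {
  k <- length(tree$contexts)
  m <- length(tree$alphabet)
  nxt <- matrix(NA_integer_, k, m,
                dimnames = list(tree$contexts, tree$alphabet))
  for (i in seq_len(k)) {
    for (j in seq_len(m)) {
      if (tree$probs[i, j] > 0) {
        d <- .match_one(tree, paste0(tree$contexts[i], tree$alphabet[j]))
        if (!is.na(d)) nxt[i, j] <- match(d, tree$contexts)
      }
    }
  }
  nxt
}

#' Simulate a stimulus sequence from a context tree
#'
#' Emits `n` symbols. The `initial` symbols are copied to the head of the
#' sequence; every later symbol is drawn from the distribution of the context
#' matching the history so far. Draws consume exactly one uniform variate per
#' variable (non-degenerate) context and none per deterministic context, so a
#' fully deterministic tree yields a seed-independent sequence.
#'
#' @param tree a `context_tree`.
#' @param n number of symbols to return (>= 1).
#' @param seed optional integer seed; when given, the sequence is a pure
#'   function of `(tree, n, seed, initial, burn_in)` and the caller's RNG
#'   state is left untouched.
#' @param initial symbol string placed at the start (default `"1"`); must
#'   resolve to a matchable context by its end.
#' @param burn_in discard this many leading symbols (default 0); the returned
#'   vector still has length `n`.
#' @return character vector of `n` symbols.
#' @examples
#' generate_sequence(srt_tree(), 9, seed = 42)
#' @export
generate_sequence <- function(tree, n, seed = NULL, initial = "1",
                              burn_in = 0L) {
  stopifnot(inherits(tree, "context_tree"), n >= 1, burn_in >= 0)
  bad <- validate_tree(tree)
  if (length(bad)) stop("invalid tree: ", bad[1])
  init <- .as_symbols(initial)
  if (!all(init %in% tree$alphabet)) {
    stop("initial contains symbols outside the alphabet")
  }
  total <- n + burn_in
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  out <- character(total)
  ncopy <- min(length(init), total)
  out[seq_len(ncopy)] <- init[seq_len(ncopy)]
  if (total > length(init)) {
    ctx <- .match_one(tree, paste(init, collapse = ""))
    if (is.na(ctx)) {
      stop("`initial` does not resolve to a context; generation cannot start")
    }
    ci <- match(ctx, tree$contexts)
    nxt <- .context_transitions(tree)
    det <- tree$deterministic
    fixed_sym <- apply(tree$probs, 1L, which.max)  # emission for det contexts
    cum <- t(apply(tree$probs, 1L, cumsum))
    for (t in (length(init) + 1L):total) {
      if (det[ci]) {
        a <- fixed_sym[ci]
      } else {
        a <- findInterval(stats::runif(1L), cum[ci, ]) + 1L
      }
      out[t] <- tree$alphabet[a]
      ci <- nxt[ci, a]
      if (is.na(ci)) {
        stop("unmatchable history during generation; the tree is incomplete")
      }
    }
  }
  out[(burn_in + 1L):total]
}

# classify each alphabet symbol by the contexts that can emit it:
# "F" if all emitting contexts are deterministic, "V" if all are variable,
# NA if mixed or never emitted. Used to label leading symbols that have no
# matchable context yet.
.symbol_class <- function(tree) {
  vapply(tree$alphabet, function(a) {
    emit <- tree$probs[, a] > 0
    if (!any(emit)) return(NA_character_)
    d <- tree$deterministic[emit]
    if (all(d)) "F" else if (!any(d)) "V" else NA_character_
  }, character(1))
}

#' Label stimuli as fixed or variable events
#'
#' Each position is labeled `F<symbol>` when its generating context is
#' deterministic and `V<symbol>` when it is variable (for the SRT tree:
#' F1, F2, V2, V3). Leading positions with no matchable context inherit the
#' symbol's class when it is unambiguous across the whole tree (a leading 1
#' on the SRT tree is F1), and are `UNKNOWN` otherwise. A symbol with zero
#' probability under its matched context raises a warning but is still
#' labeled by its symbol.
#'
#' @param tree a `context_tree`.
#' @param symbols character vector of observed symbols (or one string).
#' @return character vector of event labels, same length as `symbols`.
#' @examples
#' label_events(srt_tree(), c("1","2","3","1","2","2","1","2","3"))
#' @export
label_events <- function(tree, symbols) {
  stopifnot(inherits(tree, "context_tree"))
  symbols <- .as_symbols(symbols)
  if (length(symbols) == 0L) return(character(0))
  if (!all(symbols %in% tree$alphabet)) {
    stop("symbols outside the tree's alphabet")
  }
  ctx <- .match_seq(tree, symbols)
  matched <- !is.na(ctx)
  lab <- rep("UNKNOWN", length(symbols))
  if (any(matched)) {
    ci <- match(ctx[matched], tree$contexts)
    det <- tree$deterministic[ci]
    p <- tree$probs[cbind(ci, match(symbols[matched], tree$alphabet))]
    lab[matched] <- paste0(ifelse(det, "F", "V"), symbols[matched])
    if (any(p == 0)) {
      warning(sprintf(
        "%d symbol(s) have zero probability under their matched context",
        sum(p == 0)))
      # impossible under the matched context: fall back to the symbol's own
      # fixed/variable class when it is unambiguous across the tree
      cls <- .symbol_class(tree)[symbols[matched][p == 0]]
      lab[matched][p == 0] <- ifelse(
        is.na(cls), lab[matched][p == 0],
        paste0(cls, symbols[matched][p == 0]))
    }
  }
  if (any(!matched)) {
    cls <- .symbol_class(tree)[symbols[!matched]]
    lab[!matched] <- ifelse(is.na(cls), "UNKNOWN",
                            paste0(cls, symbols[!matched]))
  }
  lab
}

#' Annotate each trial with its last variable event
#'
#' For each position, reports the label of the most recent strictly
#' preceding variable (V-labeled) event, or `"NONE"` when no variable event
#' has occurred yet. This is the conditioning factor of the
#' event-by-last-variable-event analysis.
#'
#' @param labels character vector of event labels from [label_events()].
#' @return character vector over the V-labels and `"NONE"`, same length.
#' @examples
#' annotate_last_variable(c("F1","F2","V3","F1","F2","V2","F1"))
#' @export
annotate_last_variable <- function(labels) {
  n <- length(labels)
  if (n == 0L) return(character(0))
  isv <- startsWith(labels, "V")
  lastv <- cummax(ifelse(isv, seq_len(n), 0L))   # index of last V up to t
  prev <- c(0L, lastv[-n])                       # strictly preceding
  out <- rep("NONE", n)
  has <- prev > 0L
  out[has] <- labels[prev[has]]
  out
}

#' Long-run event frequencies of a context tree
#'
#' Solves the stationary distribution of the induced Markov chain on
#' contexts and folds it into event labels: the long-run frequency of label
#' `F<a>`/`V<a>` is the stationary mass of deterministic/variable contexts
#' emitting `a`, weighted by the emission probability. For the SRT tree this
#' gives F1 = F2 = 1/3, V2 = 0.26/3, V3 = 0.74/3.
#'
#' @param tree a valid, irreducible `context_tree`.
#' @return named numeric vector of frequencies summing to 1.
#' @export
stationary_event_frequencies <- function(tree) {
  stopifnot(inherits(tree, "context_tree"))
  bad <- validate_tree(tree)
  if (length(bad)) stop("invalid tree: ", bad[1])
  k <- length(tree$contexts)
  nxt <- .context_transitions(tree)
  P <- matrix(0, k, k, dimnames = list(tree$contexts, tree$contexts))
  for (i in seq_len(k)) {
    for (j in seq_along(tree$alphabet)) {
      if (tree$probs[i, j] > 0) P[i, nxt[i, j]] <- P[i, nxt[i, j]] +
          tree$probs[i, j]
    }
  }
  # irreducibility: (I + P)^(k-1) must be positive
  reach <- diag(k) + P
  acc <- reach
  if (k > 1) for (s in seq_len(k - 1)) acc <- acc %*% reach
  if (any(acc == 0)) {
    stop("context chain is reducible; no unique stationary distribution")
  }
  # left stationary vector: solve pi (P - I) = 0, sum(pi) = 1
  A <- rbind(t(P) - diag(k), rep(1, k))
  pi_ctx <- qr.solve(A, c(rep(0, k), 1))
  pi_ctx <- pmax(pi_ctx, 0)
  pi_ctx <- pi_ctx / sum(pi_ctx)
  labs <- outer(ifelse(tree$deterministic, "F", "V"), tree$alphabet, paste0)
  freq <- tapply(as.vector(tree$probs * pi_ctx), as.vector(labs), sum)
  freq <- freq[freq > 0]
  c(freq)
}

#' Expected event counts over a session
#'
#' Multiplies the analytic stationary event frequencies by the number of
#' trials. For a 750-trial session on the SRT tree: F1 = 250, F2 = 250,
#' V2 = 65, V3 = 185.
#'
#' @param tree a valid `context_tree`.
#' @param n number of trials (>= 0).
#' @return named numeric vector of expected counts.
#' @examples
#' expected_event_counts(srt_tree(), 750)
#' @export
expected_event_counts <- function(tree, n) {
  stopifnot(n >= 0)
  n * stationary_event_frequencies(tree)
}

#' Read / write a context tree as JSON
#'
#' The interchange format is a JSON object with fields `alphabet` (list of
#' single-character symbols) and `contexts` (map from context string to a
#' probability list aligned with the alphabet order). The packaged SRT tree
#' ships at `system.file("extdata", "srt_tree.json", package = "ctsrt")`.
#'
#' @param path file path.
#' @return `read_tree` returns a `context_tree`; `write_tree` returns `path`
#'   invisibly.
#' @export
read_tree <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$alphabet) || is.null(cfg$contexts)) {
    stop("tree JSON must have `alphabet` and `contexts` fields")
  }
  context_tree(as.list(cfg$contexts), alphabet = unlist(cfg$alphabet))
}

#' @rdname read_tree
#' @param tree a `context_tree`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "context_tree"))
  obj <- list(alphabet = tree$alphabet,
              contexts = stats::setNames(
                lapply(seq_along(tree$contexts),
                       function(i) tree$probs[i, ]),
                tree$contexts))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
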