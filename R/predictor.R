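#' One-hot encoding of a residue window
#'
#' Encodes the window centred on an acceptor residue as the concatenation of
#' one-hot blocks of length 21 (20 amino acids + X, which doubles as the
#' terminal pad and unknown-residue symbol), the input representation of
#' classical sliding-window phosphorylation/glycosylation networks.
#'
#' @param record A [protein_record()].
#' @param position Reported position; the residue there must be S, T or Y.
#' @param window Odd window width in residues (default 9, centre +/- 4).
#' @return Numeric 0/1 vector of length `window * 21`, one 1 per block.
#' @export
encode_window <- function(record, position, window = 9L) {
  stopifnot(inherits(record, "protein_record"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  centre <- residue_at(record, position)
  if (!centre %in% c("S", "T", "Y"))
    stop(sprintf("window centre must be S/T/Y, got %s at %s:%d",
                 centre, record$id, position), call. = FALSE)
  chars <- .seq_chars(record$sequence)
  raw <- as.integer(position) - record$numbering_offset
  half <- window %/% 2L
  idx <- (raw - half):(raw + half)
  res <- ifelse(idx >= 1L & idx <= length(chars), chars[pmax(idx, 1L)], "X")
  res[res == "X" | !res %in% AA21] <- "X"
  v <- numeric(window * 21L)
  v[(seq_len(window) - 1L) * 21L + match(res, AA21)] <- 1
  v
}

# window matrix for a set of (record, position) pairs
.encode_matrix <- function(records, sites, window) {
  if (inherits(records, "protein_record")) records <- list(records)
  byid <- setNames(records, vapply(records, `[[`, "", "id"))
  t(vapply(seq_len(nrow(sites)), function(i) {
    rec <- byid[[sites$seq_id[i]]]
    if (is.null(rec))
      stop(sprintf("no record for seq_id '%s'", sites$seq_id[i]), call. = FALSE)
    encode_window(rec, sites$position[i], window)
  }, numeric(window * 21L)))
}

# forward pass through a single-hidden-layer logistic network given the
# nnet weight layout: per hidden unit (bias, inputs...), then (bias, hidden...)
.nn_forward <- function(wts, size, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  nin <- ncol(x)
  H <- vapply(seq_len(size), function(h) {
    w <- wts[((h - 1L) * (nin + 1L) + 1L):(h * (nin + 1L))]
    plogis(w[1L] + drop(x %*% w[-1L]))
  }, numeric(nrow(x)))
  if (is.null(dim(H))) H <- matrix(H, nrow = nrow(x))
  wo <- wts[(size * (nin + 1L) + 1L):(size * (nin + 1L) + size + 1L)]
  plogis(wo[1L] + drop(H %*% wo[-1L]))
}

#' Train a sliding-window neural site scorer
#'
#' Fits a single-hidden-layer feed-forward network (logistic activations,
#' cross-entropy fit via [nnet::nnet()], weight decay, fixed epoch cap) on
#' one-hot encoded windows, and estimates held-out accuracy by k-fold
#' cross-validation.  All randomness (fold assignment, weight
#' initialisation) flows from the single `seed`.
#'
#' @param records List of [protein_record()]s providing the sequence context.
#' @param examples data.frame with columns `seq_id`, `position`, `label`
#'   (0/1 or logical); both classes must be present.
#' @param window Odd window width (default 9).
#' @param folds Number of CV folds (default 5, >= 2).
#' @param seed Integer seed controlling all randomness.
#' @param epochs Optimiser iteration cap (default 200).
#' @param hidden Hidden units (default 4).
#' @param decay Weight decay (default 1e-4).
#' @param threshold Positive-call threshold stored with the model (default 0.5).
#' @param predictor Label for emitted scores: `"phospho"` (scores S/T/Y) or
#'   `"glyco"` (scores S/T).
#' @return Object of class `yy_model`: window, alphabet, hidden size, weight
#'   vector, threshold, predictor, and `training_meta` (folds, seed, epochs,
#'   per-fold and mean held-out accuracy, n).
#' @export
train_predictor <- function(records, examples, window = 9L, folds = 5L,
                            seed = 1L, epochs = 200L, hidden = 4L,
                            decay = 1e-4, threshold = 0.5,
                            predictor = c("phospho", "glyco")) {
  predictor <- match.arg(predictor)
  stopifnot(folds >= 2L, threshold > 0, threshold < 1)
  y <- as.integer(as.logical(examples$label))
  if (length(unique(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  X <- .encode_matrix(records, examples, window)
  n <- nrow(X)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(folds), length.out = n))
  acc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- fold != k
    fit <- nnet::nnet(X[tr, , drop = FALSE], y[tr], size = hidden,
                      entropy = TRUE, decay = decay, maxit = epochs,
                      trace = FALSE, MaxNWts = 100000L)
    p <- .nn_forward(fit$wts, hidden, X[!tr, , drop = FALSE])
    acc[k] <- mean((p >= threshold) == (y[!tr] == 1L))
  }
  fit <- nnet::nnet(X, y, size = hidden, entropy = TRUE, decay = decay,
                    maxit = epochs, trace = FALSE, MaxNWts = 100000L)
  structure(list(window = as.integer(window), alphabet = AA21,
                 hidden = as.integer(hidden), wts = as.numeric(fit$wts),
                 threshold = threshold, predictor = predictor,
                 training_meta = list(folds = as.integer(folds),
                                      seed = as.integer(seed),
                                      epochs = as.integer(epochs),
                                      decay = decay,
                                      fold_accuracy = acc,
                                      heldout_accuracy = mean(acc),
                                      n = n)),
            class = "yy_model")
}

#' @export
print.yy_model <- function(x, ...) {
  cat(sprintf("yy_model (%s): window %d, %d hidden units, threshold %.2f, held-out accuracy %.3f (n=%d)\n",
              x$predictor, x$window, x$hidden, x$threshold,
              x$training_meta$heldout_accuracy, x$training_meta$n))
  invisible(x)
}

#' Score candidate acceptor residues of a sequence
#'
#' Emits one score row per S/T residue (plus Y for a phospho model); a site
#' is positive iff `score >= threshold`.
#'
#' @param model A `yy_model` from [train_predictor()] or [load_model()].
#' @param record A [protein_record()].
#' @return Score data.frame in the [read_score_table()] shape.
#' @export
predict_sites <- function(model, record) {
  stopifnot(inherits(model, "yy_model"), inherits(record, "protein_record"))
  if (!identical(model$alphabet, AA21))
    stop("model alphabet does not match this package's encoding", call. = FALSE)
  targets <- if (model$predictor == "phospho") c("S", "T", "Y") else c("S", "T")
  chars <- .seq_chars(record$sequence)
  at <- which(chars %in% targets)
  if (!length(at))
    return(data.frame(seq_id = character(), position = integer(),
                      residue = character(), predictor = character(),
                      score = numeric(), threshold = numeric(),
                      stringsAsFactors = FALSE))
  pos <- at + record$numbering_offset
  X <- t(vapply(pos, function(p) encode_window(record, p, model$window),
                numeric(model$window * 21L)))
  data.frame(seq_id = record$id, position = pos, residue = chars[at],
             predictor = model$predictor,
             score = .nn_forward(model$wts, model$hidden, X),
             threshold = model$threshold, stringsAsFactors = FALSE)
}

#' Save / load a scorer as self-describing JSON
#'
#' The file stores the architecture, alphabet, full-precision weights and
#' training metadata; a reloaded model reproduces scores bit-identically.
#'
#' @param model A `yy_model`.
#' @param path File path.
#' @return `path` invisibly for `save_model`; a `yy_model` for `load_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "yy_model"))
  out <- unclass(model)
  # %.17g round-trips IEEE doubles exactly, so a reloaded model scores
  # bit-identically
  out$wts <- sprintf("%.17g", out$wts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$window <- as.integer(m$window)
  m$hidden <- as.integer(m$hidden)
  m$wts <- as.numeric(m$wts)
  m$threshold <- as.numeric(m$threshold)
  for (f in c("fold_accuracy", "heldout_accuracy", "decay"))
    m$training_meta[[f]] <- as.numeric(m$training_meta[[f]])
  structure(m, class = "yy_model")
}

#' Import an external predictor's score table
#'
#' External servers (NetPhos-, NetPhosK-, YinOYang-style) are consumed, not
#' re-implemented: their exports are read as typed score rows carrying their
#' own thresholds.
#'
#' @param path Score TSV ([read_score_table()] columns).
#' @param predictor Optional filter on the `predictor` column.
#' @param records Optional records for residue cross-checking.
#' @return Score data.frame.
#' @export
import_scores <- function(path, predictor = NULL, records = NULL) {
  df <- read_score_table(path, records = records)
  if (!is.null(predictor)) df <- df[df$predictor %in% predictor, , drop = FALSE]
  rownames(df) <- NULL
  df
}
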