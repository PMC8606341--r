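#' Construct a class HMM topology model
#'
#' A `topology_model` holds the structure shared by the CHMM and the HNN: a
#' set of states linked by a row-stochastic transition matrix `a_kl`, an
#' initial (begin) distribution, and a delta-function label map assigning
#' each state exactly one label. Emissions are either a per-state (or
#' per-tying-group) probability table over the alphabet (CHMM mode) or a map
#' from states to emission networks over a windowed context (HNN mode).
#'
#' Structural zeros — transitions the grammar forbids — are recorded in the
#' `allowed` mask and stay exactly 0 through training; all other transition
#' probabilities are kept above a pseudocount floor.
#'
#' @param states character vector of state ids.
#' @param label_map named character vector, one label per state.
#' @param begin named numeric begin distribution (missing states get 0).
#' @param trans square transition matrix with `states` as dimnames, rows
#'   summing to 1 over allowed successors.
#' @param emissions either a numeric matrix (tying groups x alphabet,
#'   rownames = tying-group ids) for CHMM mode, a named list of
#'   [emission_network()] objects (one per state) for HNN mode, or `NULL`
#'   for an untrained grammar.
#' @param tie named character vector mapping each state to a tying-group id;
#'   states in one group share emission parameters. Default: one group per
#'   state, named by the state.
#' @param end_states optional character vector of designated end states;
#'   `NULL` means a free end (sum over all states at position L).
#' @param alphabet residue alphabet.
#' @param window a [window_spec()] (HNN mode).
#' @param encoding `"onehot"` or `"profile"` context encoding (HNN mode).
#' @param allowed optional logical matrix of structurally allowed
#'   transitions; defaults to `trans > 0`.
#' @return An object of class `topology_model`.
#' @export
topology_model <- function(states, label_map, begin, trans,
                           emissions = NULL, tie = NULL, end_states = NULL,
                           alphabet = aa_alphabet(), window = NULL,
                           encoding = c("onehot", "profile"),
                           allowed = NULL) {
  encoding <- match.arg(encoding)
  S <- length(states)
  stopifnot(S >= 1, !anyDuplicated(states))
  trans <- as.matrix(trans)
  stopifnot(nrow(trans) == S, ncol(trans) == S)
  dimnames(trans) <- list(states, states)
  if (is.null(allowed)) allowed <- trans > 0
  dimnames(allowed) <- dimnames(trans)
  b <- stats::setNames(numeric(S), states)
  b[names(begin)] <- begin
  if (is.null(tie)) tie <- stats::setNames(states, states)
  mode <- if (is.null(emissions)) "none"
          else if (is.matrix(emissions)) "table" else "network"
  m <- structure(
    list(states = states, labels = sort(unique(unname(label_map))),
         label_map = label_map[states], begin = b, trans = trans,
         allowed = allowed, emissions = emissions, emission_mode = mode,
         tie = tie[states], end_states = end_states, alphabet = alphabet,
         window = window, encoding = encoding),
    class = "topology_model")
  validate_topology_model(m)
  m
}

#' Validate a topology model's invariants
#'
#' Checks that every transition row and the begin distribution sum to 1
#' within `1e-10` over allowed entries, that each state carries exactly one
#' label, that emission-table rows are probability vectors, and that
#' forbidden transitions are exactly 0.
#'
#' @param model a [topology_model()].
#' @return `model`, invisibly; errors on violation.
#' @export
validate_topology_model <- function(model) {
  S <- length(model$states)
  if (any(model$trans[!model$allowed] != 0))
    stop("structurally forbidden transitions must be exactly 0")
  rs <- rowSums(model$trans)
  dead <- rowSums(model$allowed) == 0
  if (any(abs(rs[!dead] - 1) > 1e-10))
    stop("transition rows must sum to 1 within 1e-10")
  if (abs(sum(model$begin) - 1) > 1e-10)
    stop("begin distribution must sum to 1 within 1e-10")
  if (any(is.na(model$label_map)) || length(model$label_map) != S)
    stop("label_map must assign every state exactly one label")
  if (model$emission_mode == "table") {
    e <- model$emissions
    if (ncol(e) != length(model$alphabet))
      stop("emission table must have one column per alphabet symbol")
    if (!all(unique(model$tie) %in% rownames(e)))
      stop("every tying group needs an emission-table row")
    if (any(e < 0) || any(abs(rowSums(e) - 1) > 1e-10))
      stop("emission rows must be probability vectors (sum 1 within 1e-10)")
  }
  if (model$emission_mode == "network") {
    if (!all(model$states %in% names(model$emissions)))
      stop("every state needs an emission network")
    if (is.null(model$window)) stop("HNN mode requires a window spec")
  }
  invisible(model)
}

#' @export
print.topology_model <- function(x, ...) {
  cat("<topology_model> ", length(x$states), " states, labels {",
      paste(x$labels, collapse = ","), "}, emissions: ",
      x$emission_mode, "\n", sep = "")
  if (x$emission_mode == "network")
    cat("  window K = ", x$window$K, " (", x$window$left, "+1+",
        x$window$right, "), encoding ", x$encoding, "\n", sep = "")
  invisible(x)
}

#' Tidy a topology model into a transition table
#'
#' @param x a [topology_model()].
#' @param ... unused.
#' @return Tibble with columns `from`, `to`, `prob` over allowed transitions.
#' @export
tidy.topology_model <- function(x, ...) {
  idx <- which(x$allowed, arr.ind = TRUE)
  tibble::tibble(from = x$states[idx[, 1]], to = x$states[idx[, 2]],
                 prob = x$trans[idx])[order(idx[, 1], idx[, 2]), ]
}

label_mask <- function(model, labels) {
  # L x S logical: state k admissible at position i under clamping
  outer(labels, model$label_map[model$states], `==`)
}

#' Read a model or grammar file
#'
#' Flat-text format with `[section]` headers and `key = value` pairs;
#' sections: `model` (alphabet, states, labels, label map, begin, tying,
#' end policy, encoding, window), `transitions` (one `from to prob` triple
#' per line), `emissions` (CHMM tables) or `network <state>` blocks (HNN
#' weights). Trained models round-trip exactly through
#' [write_model()]/[read_model()].
#'
#' @param path model file.
#' @return A [topology_model()].
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec_at <- grep("^\\[.*\\]$", lines)
  secs <- sub("^\\[(.*)\\]$", "\\1", lines[sec_at])
  sec_end <- c(sec_at[-1] - 1L, length(lines))
  get_sec <- function(name) {
    j <- which(secs == name)
    if (length(j) == 0L) return(character(0))
    unlist(lapply(j, function(i) {
      if (sec_end[i] < sec_at[i] + 1L) character(0)
      else lines[(sec_at[i] + 1L):sec_end[i]]
    }))
  }
  kv <- function(ls) {
    has <- grepl("=", ls, fixed = TRUE)
    keys <- trimws(sub("=.*$", "", ls[has]))
    vals <- trimws(sub("^[^=]*=", "", ls[has]))
    stats::setNames(as.list(vals), keys)
  }
  meta <- kv(get_sec("model"))
  split_csv <- function(s) trimws(strsplit(s, ",")[[1]])
  alphabet <- strsplit(meta$alphabet, "")[[1]]
  states <- split_csv(meta$states)
  lm_pairs <- strsplit(split_csv(meta$label_map), ":")
  label_map <- stats::setNames(vapply(lm_pairs, `[`, "", 2),
                               vapply(lm_pairs, `[`, "", 1))
  bg_pairs <- strsplit(split_csv(meta$begin), ":")
  begin <- stats::setNames(as.numeric(vapply(bg_pairs, `[`, "", 2)),
                           vapply(bg_pairs, `[`, "", 1))
  tie <- NULL
  if (!is.null(meta$tie)) {
    tp <- strsplit(split_csv(meta$tie), ":")
    tie <- stats::setNames(vapply(tp, `[`, "", 2), vapply(tp, `[`, "", 1))
  }
  end_states <- if (!is.null(meta$end_states)) split_csv(meta$end_states)
  S <- length(states)
  trans <- matrix(0, S, S, dimnames = list(states, states))
  allowed <- matrix(FALSE, S, S, dimnames = list(states, states))
  for (ln in get_sec("transitions")) {
    f <- strsplit(ln, "\\s+")[[1]]
    trans[f[1], f[2]] <- as.numeric(f[3])
    allowed[f[1], f[2]] <- TRUE
  }
  emissions <- NULL
  window <- NULL
  encoding <- if (is.null(meta$encoding)) "onehot" else meta$encoding
  if (!is.null(meta$window))
    window <- do.call(window_spec, as.list(as.integer(split_csv(meta$window))))
  em_lines <- get_sec("emissions")
  if (length(em_lines) > 0L) {
    parts <- strsplit(em_lines, "\\s+")
    emissions <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
    rownames(emissions) <- vapply(parts, `[`, "", 1)
  }
  net_secs <- grep("^network ", secs, value = TRUE)
  if (length(net_secs) > 0L) {
    emissions <- list()
    for (ns in net_secs) {
      st <- sub("^network ", "", ns)
      emissions[[st]] <- parse_network_block(get_sec(ns))
    }
  }
  topology_model(states, label_map, begin, trans, emissions = emissions,
                 tie = tie, end_states = end_states, alphabet = alphabet,
                 window = window, encoding = encoding, allowed = allowed)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

parse_network_block <- function(ls) {
  kv <- strsplit(ls, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  H <- as.integer(vals$hidden)
  D <- as.integer(vals$input_dim)
  emission_network(
    input_dim = D, hidden = H, activation = vals$activation,
    W1 = matrix(nums(vals$W1), nrow = H, ncol = D, byrow = TRUE),
    b1 = nums(vals$b1), w2 = nums(vals$w2), b2 = nums(vals$b2))
}

#' Write a model or grammar file
#'
#' @param model a [topology_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [read_model()] for the format.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# hnntm model file; coordinates in reports are 1-based closed intervals")
  w("[model]")
  w("alphabet = ", paste(model$alphabet, collapse = ""))
  w("states = ", paste(model$states, collapse = ","))
  w("label_map = ", paste(model$states, model$label_map[model$states],
                          sep = ":", collapse = ","))
  nz <- model$begin > 0
  w("begin = ", paste(names(model$begin)[nz], fmt_num(model$begin[nz]),
                      sep = ":", collapse = ","))
  w("tie = ", paste(model$states, model$tie[model$states],
                    sep = ":", collapse = ","))
  if (!is.null(model$end_states))
    w("end_states = ", paste(model$end_states, collapse = ","))
  w("encoding = ", model$encoding)
  if (!is.null(model$window))
    w("window = ", model$window$left, ",", model$window$right)
  w("[transitions]")
  idx <- which(model$allowed, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  for (r in seq_len(nrow(idx)))
    w(model$states[idx[r, 1]], " ", model$states[idx[r, 2]], " ",
      fmt_num(model$trans[idx[r, 1], idx[r, 2]]))
  if (model$emission_mode == "table") {
    w("[emissions]")
    for (g in rownames(model$emissions))
      w(g, " ", paste(fmt_num(model$emissions[g, ]), collapse = " "))
  }
  if (model$emission_mode == "network") {
    for (st in model$states) {
      net <- model$emissions[[st]]
      w("[network ", st, "]")
      w("input_dim = ", net$input_dim)
      w("hidden = ", net$hidden)
      w("activation = ", net$activation)
      w("W1 = ", paste(fmt_num(t(net$W1)), collapse = " "))
      w("b1 = ", paste(fmt_num(net$b1), collapse = " "))
      w("w2 = ", paste(fmt_num(net$w2), collapse = " "))
      w("b2 = ", fmt_num(net$b2))
    }
  }
  invisible(path)
}
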