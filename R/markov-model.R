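EPS_P <- 1e-12

.word_strings <- function(k) {
    idx <- 0:(4L^k - 1L)
    out <- character(length(idx))
    w <- idx
    for (j in seq_len(k)) {
        out <- paste0(CODE_LETTERS[w %% 4L + 1L], out)
        w <- w %/% 4L
    }
    out
}

#' Fit an order-k Markov model from unambiguous runs
#'
#' Word probabilities pi(w) are the empirical frequencies of k-words over
#' all word positions in the unambiguous runs; transition probabilities
#' trans(w, b) come from (word, next base) adjacencies counted strictly
#' within runs (never across an ambiguity separator).  Words never seen in
#' a transition context get a uniform row; words never seen at all get
#' pi = 0.
#'
#' @param chroms a \linkS4class{MaskedChromosome} or list thereof; counts
#'   are pooled over everything supplied.
#' @param k model order = word length.
#' @param source label recorded in the model ("global", or the chromosome
#'   name when fitting per chromosome).
#' @return a \linkS4class{MarkovModel}.
#' @export
fitMarkov <- function(chroms, k, source = NULL) {
    if (methods::is(chroms, "MaskedChromosome")) chroms <- list(chroms)
    stopifnot(length(chroms) >= 1L, k >= 1L)
    nw <- 4L^k
    wcount <- numeric(nw)
    tcount <- numeric(nw * 4L)
    any_run <- FALSE
    for (ch in chroms) {
        codes <- ch@codes
        if (any(IRanges::width(ch@runs) > k)) any_run <- TRUE
        wc <- wordCodes(codes, k)
        ok <- !is.na(wc)
        wcount <- wcount + tabulate(wc[ok] + 1L, nbins = nw)
        # adjacency (w at i, base at i+k): valid iff the k+1-span is unmasked
        L <- length(codes)
        if (L >= k + 1L) {
            i <- seq_len(L - k)
            nxt <- codes[i + k]
            sel <- ok[i] & nxt < 4L
            if (any(sel))
                tcount <- tcount +
                    tabulate(wc[i][sel] * 4L + nxt[sel] + 1L, nbins = nw * 4L)
        }
    }
    if (!any_run)
        stop("no unambiguous run longer than k = ", k, "; cannot fit model")
    if (sum(wcount) == 0)
        stop("no unambiguous word of length k = ", k, " observed")
    pi <- wcount / sum(wcount)
    trans <- matrix(tcount, nrow = nw, ncol = 4L, byrow = TRUE)
    rs <- rowSums(trans)
    unseen <- rs == 0
    trans[unseen, ] <- 0.25
    trans[!unseen, ] <- trans[!unseen, , drop = FALSE] / rs[!unseen]
    if (is.null(source))
        source <- if (length(chroms) == 1L) chromName(chroms[[1L]]) else "global"
    new("MarkovModel", k = as.integer(k), pi = pi, trans = trans,
        source = source)
}

#' Preset background models
#'
#' \code{"uniform"}: i.i.d. equiprobable bases.  \code{"gcskew"}: i.i.d.
#' with GC content 0.41 (close to the human genome), A=T=0.295,
#' C=G=0.205.  Both are expressed as order-k models (product pi, base
#' marginal in every transition row) so any k works downstream.
#'
#' @param preset "uniform" or "gcskew".
#' @param k model order.
#' @return a \linkS4class{MarkovModel}.
#' @export
presetModel <- function(preset = c("uniform", "gcskew"), k = 3L) {
    preset <- match.arg(preset)
    base <- switch(preset,
        uniform = rep(0.25, 4),
        gcskew  = c(0.295, 0.205, 0.205, 0.295))
    nw <- 4L^k
    w <- 0:(nw - 1L)
    pi <- rep(1, nw)
    for (j in seq_len(k)) {
        pi <- pi * base[w %% 4L + 1L]
        w <- w %/% 4L
    }
    trans <- matrix(base, nrow = nw, ncol = 4L, byrow = TRUE)
    new("MarkovModel", k = as.integer(k), pi = pi, trans = trans,
        source = preset)
}

# one-base-shift word-to-word transition matrix, sparse 4^k x 4^k
.shift_matrix <- function(model) {
    k <- model@k
    nw <- 4L^k
    w <- rep(0:(nw - 1L), each = 4L)
    b <- rep(0:3L, nw)
    nxt <- (w %% 4L^(k - 1L)) * 4L + b
    Matrix::sparseMatrix(i = w + 1L, j = nxt + 1L,
                         x = as.vector(t(model@trans)), dims = c(nw, nw))
}

# F[u, w] = P(the next k emitted symbols spell the reverse complement of
# word w | chain state u); deterministic state path, so O(k * 4^(2k)).
.emission_matrix <- function(model, rcmap) {
    k <- model@k
    nw <- 4L^k
    u0 <- 0:(nw - 1L)
    keep <- 4L^(k - 1L)
    FF <- matrix(0, nw, nw)
    for (w in 0:(nw - 1L)) {
        target <- rcmap[w + 1L]
        # digits of target, most significant first
        s <- integer(k)
        tt <- target
        for (j in k:1) { s[j] <- tt %% 4L; tt <- tt %/% 4L }
        state <- u0
        prob <- rep(1, nw)
        for (j in seq_len(k)) {
            prob <- prob * model@trans[state + 1L, s[j] + 1L]
            state <- (state %% keep) * 4L + s[j]
        }
        FF[, w + 1L] <- prob
    }
    FF
}

#' Expected pair probability p(d) under the Markov null
#'
#' p(d) is the probability that a k-word occurrence is followed, at
#' start-to-start distance d, by its reverse complement.  For loop (gap)
#' lengths g = d - k up to \code{horizon} it is computed exactly: start
#' the chain in word w (weight pi(w)), propagate g one-base steps, then
#' chain the k transition probabilities that spell out the reverse
#' complement of w; summed over words.  Beyond the horizon the stationary
#' approximation p_inf = pi-averaged probability of meeting the reverse
#' complement is used (the propagated state distribution converges to pi,
#' so p(d) is flat there).  Exact propagation costs O(horizon * 4^(2k));
#' for k > 5 the function falls back to horizon = 0 (the stationary /
#' independence approximation, p_inf = sum_w pi(w) pi(rc(w))) with a
#' message.
#'
#' @param model a \linkS4class{MarkovModel}.
#' @param dmax maximum distance (default 4000).
#' @param horizon gap length up to which exact propagation is used
#'   (default 50; DNA chains mix fast, the tail is flat).
#' @return a \linkS4class{PairProbability}; probabilities are clipped to
#'   [1e-12, 1 - 1e-12] and the object is flagged degenerate if clipping
#'   was active.
#' @export
pairProbability <- function(model, dmax = 4000L, horizon = 50L) {
    k <- model@k
    stopifnot(dmax >= k, horizon >= 0L)
    nw <- 4L^k
    rcmap <- rcWordMap(k)
    pi <- model@pi
    exact <- k <= 5L
    if (!exact && horizon > 0L) {
        message("k > 5: exact loop propagation disabled, using the ",
                "stationary approximation (horizon = 0)")
        horizon <- 0L
    }
    gmax <- dmax - k
    p <- numeric(gmax + 1L)
    if (exact) {
        FF <- .emission_matrix(model, rcmap)
        A <- .shift_matrix(model)
        p_inf <- sum(pi * as.numeric(pi %*% FF))
        Mg <- diag(nrow = nw)     # A^g, dense
        for (g in 0:min(horizon, gmax)) {
            p[g + 1L] <- sum(pi * rowSums(Mg * t(FF)))
            if (g < min(horizon, gmax)) Mg <- as.matrix(Mg %*% A)
        }
        if (gmax > horizon) p[(horizon + 2L):(gmax + 1L)] <- p_inf
    } else {
        # g = 0 (adjacent words) is still exact and cheap: only the
        # diagonal of the emission matrix is needed
        keep <- 4L^(k - 1L)
        diagF <- rep(1, nw)
        state <- 0:(nw - 1L)
        targ <- rcmap + 0L
        sdig <- matrix(0L, nw, k)
        tt <- targ
        for (j in k:1) { sdig[, j] <- tt %% 4L; tt <- tt %/% 4L }
        st <- state
        for (j in seq_len(k)) {
            diagF <- diagF * model@trans[cbind(st + 1L, sdig[, j] + 1L)]
            st <- (st %% keep) * 4L + sdig[, j]
        }
        p[1L] <- sum(pi * diagF)
        p_inf <- sum(pi * pi[rcmap + 1L])
        if (gmax >= 1L) p[2:(gmax + 1L)] <- p_inf
    }
    clipped <- p < EPS_P | p > 1 - EPS_P
    p <- pmin(pmax(p, EPS_P), 1 - EPS_P)
    new("PairProbability", k = k, dmax = as.integer(dmax), p = p,
        horizon = as.integer(horizon), degenerate = any(clipped))
}

#' Simulate a control-scenario chromosome
#'
#' Generates a sequence with the same length and the exact same ambiguous
#' positions as the template; each unambiguous run is drawn independently
#' from the model (first k symbols from pi, the rest from the transition
#' rows; runs shorter than k take the leading symbols of a pi-drawn
#' word).  The chain restarts at every run boundary: separators terminate
#' dependence.  Identical seed implies identical output.
#'
#' @param model a \linkS4class{MarkovModel}.
#' @param template a \linkS4class{MaskedChromosome} supplying length and
#'   N-mask.
#' @param seed integer seed; if NULL the current RNG state is used.
#' @param name name for the simulated chromosome (default: template name).
#' @return a \linkS4class{MaskedChromosome}.
#' @export
simulateSequence <- function(model, template, seed = NULL,
                             name = chromName(template)) {
    if (sum(model@pi) <= 0) stop("model has all-zero word probabilities")
    if (!is.null(seed)) set.seed(as.integer(seed))
    runs <- template@runs
    codes <- rep(4L, chromLength(template))
    if (length(runs)) {
        sim <- .simulate_runs_core(IRanges::width(runs), model@k,
                                   cumsum(model@pi),
                                   t(apply(model@trans, 1L, cumsum)))
        idx <- unlist(lapply(seq_along(runs), function(i)
            IRanges::start(runs)[i]:IRanges::end(runs)[i]))
        codes[idx] <- sim
    }
    .masked_chromosome(name, codes)
}

#' Deterministic per-chromosome child seed
#'
#' Derives a 31-bit child seed from the run seed and a chromosome index so
#' chromosome-level results do not depend on processing order.  The
#' derivation is a fixed affine map modulo 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param i 1-based chromosome index.
#' @return integer child seed.
#' @export
childSeed <- function(seed, i) {
    as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %%
               2147483647)
}

#' Serialize / restore a Markov model as versioned JSON
#'
#' Probabilities are written sparsely (observed words only), word codes as
#' ACGT strings.
#'
#' @param model a \linkS4class{MarkovModel}.
#' @param path JSON path.
#' @return \code{writeMarkovModel}: \code{path} invisibly;
#'   \code{readMarkovModel}: the restored \linkS4class{MarkovModel}.
#' @export
writeMarkovModel <- function(model, path) {
    words <- .word_strings(model@k)
    nz <- model@pi > 0
    rs_uniform <- apply(model@trans, 1L, function(r) all(r == 0.25))
    obj <- list(format = "irscape-markov", version = 1L,
                k = model@k, source = model@source,
                pi = as.list(setNames(model@pi[nz], words[nz])),
                trans = as.list(setNames(
                    lapply(which(!rs_uniform), function(i)
                        as.numeric(model@trans[i, ])),
                    words[!rs_uniform])))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeMarkovModel
#' @export
readMarkovModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "irscape-markov"))
        stop("not an irscape Markov model file: ", path)
    k <- as.integer(obj$k)
    nw <- 4L^k
    words <- .word_strings(k)
    pi <- setNames(numeric(nw), words)
    pi[names(obj$pi)] <- unlist(obj$pi)
    trans <- matrix(0.25, nw, 4L)
    if (length(obj$trans)) {
        idx <- match(names(obj$trans), words)
        for (j in seq_along(idx))
            trans[idx[j], ] <- as.numeric(obj$trans[[j]])
    }
    new("MarkovModel", k = k, pi = unname(pi), trans = trans,
        source = obj$source)
}

#' p(d) table export
#'
#' @param p a \linkS4class{PairProbability}.
#' @param path TSV output path (columns d, p).
#' @return \code{path}, invisibly.
#' @export
exportPairProbability <- function(p, path) {
    write.table(data.frame(d = distances(p), p = p@p), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
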