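#' Mid-parent heterosis value
#'
#' MPV = 100 * (F1 - MP) / MP with MP the mean of the two parental trait
#' values. Positive when the hybrid exceeds the parental average; invariant
#' to rescaling the trait's unit.
#'
#' @param f1 trait value of the hybrid.
#' @param parentF,parentM trait values of the female and male parent.
#' @return MPV as a percentage.
#' @examples
#' mpv(6, 2, 6)  # MP = 4 -> 50
#' @export
mpv <- function(f1, parentF, parentM) {
    mp <- (parentF + parentM) / 2
    if (any(mp <= 0)) stop("mid-parent value must be positive")
    100 * (f1 - mp) / mp
}

#' Heterosis group from an MPV
#'
#' Hybrids are graded on mid-parent heterosis of the trait: strictly above
#' \code{strongCut} is "strong", strictly below \code{weakCut} is "weak",
#' anything else (the boundary values included) is "middle".
#'
#' @param x MPV percentages.
#' @param strongCut,weakCut group thresholds (defaults 140 and 40).
#' @return character vector of group labels.
#' @examples
#' classifyHeterosis(c(233.98, 25.51, 140))  # strong, weak, middle
#' @export
classifyHeterosis <- function(x, strongCut = 140, weakCut = 40) {
    if (strongCut <= weakCut) stop("strongCut must exceed weakCut")
    if (any(!is.finite(x))) stop("MPV values must be finite")
    ifelse(x > strongCut, "strong", ifelse(x < weakCut, "weak", "middle"))
}

#' Per-hybrid heterosis table from a trait table and trio design
#'
#' Computes F1, MP, MPV and the heterosis group for every hybrid.
#' Replicate-level trait rows (several rows per line) are averaged per
#' line first.
#'
#' @param traits data.frame with columns \code{line} and \code{trait}
#'   (e.g. plant gross weight), covering all parents and hybrids.
#' @param design data.frame(hybrid, female, male).
#' @param strongCut,weakCut passed to [classifyHeterosis()].
#' @return data.frame(hybrid, F1, MP, MPV, group).
#' @export
heterosisTable <- function(traits, design, strongCut = 140, weakCut = 40) {
    need <- unique(c(design$hybrid, design$female, design$male))
    val <- tapply(traits$trait, traits$line, mean)
    missing <- setdiff(need, names(val))
    if (length(missing))
        stop("trait values missing for: ", paste(missing, collapse = ", "))
    f1 <- val[design$hybrid]
    mp <- (val[design$female] + val[design$male]) / 2
    m <- mpv(f1, val[design$female], val[design$male])
    data.frame(hybrid = design$hybrid, F1 = unname(f1), MP = unname(mp),
               MPV = unname(m),
               group = classifyHeterosis(m, strongCut, weakCut),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Common DEGs across the hybrids of a heterosis group
#'
#' Intersects one DEG set per hybrid — by default the union of the two
#' parent-hybrid comparisons (FH and MH) — and reports every Venn region
#' size alongside the full intersection.
#'
#' @param degSets named list of character-vector gene sets, one per
#'   hybrid.
#' @return list with \code{common} (the intersection), \code{size}, and
#'   \code{venn} — a data.frame of all 2^k - 1 membership regions with
#'   exclusive region sizes.
#' @examples
#' commonDEGs(list(h1 = c("a", "b", "c"), h2 = c("b", "c", "d"),
#'                 h3 = c("b", "c")))$common
#' @export
commonDEGs <- function(degSets) {
    if (length(degSets) == 0L) stop("need at least one DEG set")
    common <- Reduce(intersect, degSets)
    genes <- unique(unlist(degSets))
    k <- length(degSets)
    member <- vapply(degSets, function(s) genes %in% s, logical(length(genes)))
    member <- matrix(member, nrow = length(genes),
                     dimnames = list(genes, names(degSets)))
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
    venn <- data.frame(
        region = apply(combos, 1, function(z)
            paste(names(degSets)[as.logical(z)], collapse = "&")),
        size = apply(combos, 1, function(z)
            sum(apply(member, 1, function(row) all(row == as.logical(z))))),
        row.names = NULL, stringsAsFactors = FALSE)
    list(common = sort(common), size = length(common), venn = venn)
}

#' Per-hybrid DEG set for group intersection
#'
#' Selects which DEG definition feeds the group-common intersection:
#' parent-hybrid union (default), a single comparison, or the
#' parent-parent set.
#'
#' @param sets per-hybrid DEG sets from [degSets()].
#' @param which "union" (FH and MH combined), "fh", "mh" or "fm".
#' @return named list of character vectors.
#' @export
selectDegSets <- function(sets, which = c("union", "fh", "mh", "fm")) {
    which <- match.arg(which)
    lapply(sets, function(s) switch(which,
        union = union(s$FH, s$MH), fh = s$FH, mh = s$MH, fm = s$FM))
}
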