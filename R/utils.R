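# Shared internal helpers: element inference, distance kernels, contact keys.

# PDB-convention element inference from the atom name: strip leading digits
# and primes, take the first letter; two-letter elements in proteins are rare
# and handled explicitly for common ions/metals (discarded upstream anyway).
inferElement <- function(atom_name) {
    nm <- toupper(trimws(as.character(atom_name)))
    nm <- sub("^[0-9']+", "", nm)
    two <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE")
    el <- substr(nm, 1, 1)
    el[nm %in% two] <- nm[nm %in% two]
    # SE in MSE selenomethionine
    el[substr(nm, 1, 2) == "SE" & nchar(nm) <= 3] <- "SE"
    el
}

# All squared distances between two coordinate matrices (n x 3, m x 3).
crossDist2 <- function(a, b) {
    a <- as.matrix(a); b <- as.matrix(b)
    outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

crossDist <- function(a, b) {
    d2 <- crossDist2(a, b)
    d2[d2 < 0] <- 0
    sqrt(d2)
}

xyzMatrix <- function(df) {
    cbind(df$x, df$y, df$z)
}

# The two protein chain identifiers of a snapshot, in a stable order.
snapshotChains <- function(snapshot) {
    sort(unique(snapshot@atoms$chain))
}

requireTwoChains <- function(snapshot) {
    ch <- snapshotChains(snapshot)
    if (length(ch) != 2L)
        stop("snapshot must contain exactly two protein chains; found: ",
             paste(ch, collapse = ", "), call. = FALSE)
    ch
}

# Canonical string key of each contact pair, used for set operations.
contactKeys <- function(contact_set) {
    p <- if (is(contact_set, "ContactSet")) contact_set@pairs else contact_set
    if (nrow(p) == 0L) return(character(0))
    paste0(p$chain1, ":", p$resid1, "|", p$chain2, ":", p$resid2)
}

# Residue identifier strings "chain:resid" for a table with chain/resid cols.
residueKeys <- function(chain, resid) paste0(chain, ":", resid)

# Minimal distance from each water oxygen to any heavy atom in `coords`.
# Returns numeric(n_waters); Inf when coords is empty.
waterMinDist <- function(waters, coords) {
    if (nrow(waters) == 0L) return(numeric(0))
    if (nrow(coords) == 0L) return(rep(Inf, nrow(waters)))
    d2 <- crossDist2(xyzMatrix(waters), coords)
    sqrt(pmax(apply(d2, 1, min), 0))
}
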