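# sigenum — deterministic enumeration of molecules from counted ECFPs

Extended-connectivity fingerprints (ECFP) hash every circular atom
environment of a molecule, up to a radius *r*, into a fixed-length count
vector.  They are the standard representation for similarity search and
QSAR models — and they are meant to be one-way.  `sigenum` reverses them
deterministically: given a counted ECFP, it enumerates the molecular
structures that produce exactly that fingerprint.  This is useful for
auditing how much structure a fingerprint leaks and for generating
close analogues of a query molecule (all molecules sharing its ECFP).

The method works on *molecular signatures*: for each heavy atom $x$, the
atomic signature $\sigma_x^r$ is the canonical rooted fragment of all
atoms and bonds within distance $r$; the molecular signature $\Sigma_G^r$
is the multiset of these over all atoms.  Inversion solves, over an
*alphabet* $\mathcal{A}$ of (Morgan-bit multiset, atomic signature)
tuples harvested from a molecule collection, the linear Diophantine
system combining

* **PE** — per-bit partition equations
  $\sum_j n_j \, ECFP(A_j)_i = ECFP(m)_i$,
* **CE** — boundary-bond consistency
  $\#(\sigma_x^{r-1}{\to}\sigma_y^{r-1}) = \#(\sigma_y^{r-1}{\to}\sigma_x^{r-1})$,
  with even self-pairs,
* **GE** — graphicality $\sum_{i\ge2}(i-2)n_i - n_1 + 2 \in 2\mathbb{N}$,

by integer partitions per equation, orbit decomposition of coupled
candidates, compatibility-checked combination, and CE/GE filtering.
Surviving signatures are turned into molecular graphs by backtracking
over matching bond descriptors, expanded into stereoisomers, and filtered
to exact fingerprint matches.

Standard cheminformatics steps (SMILES parsing, canonicalization, Morgan
fingerprints with per-atom bit provenance, stereoisomer enumeration) are
delegated to RDKit through a bundled Python batch bridge
(`inst/python/chembridge.py`); the system requirement is a `python` on the
PATH with the `rdkit` package.  Everything else — signatures, constraint
checks, the solver, reconstruction — is plain R.

## Worked example

2-methyl-1,8-octanediol, `C[C@H](CO)CCCCCCO`:

```r
library(sigenum)

mol <- parse_smiles("C[C@H](CO)CCCCCCO")[[1]]
fp  <- counted_ecfp(mol)      # radius 2, 2048 bits, chirality on
fp
#> <counted_fp> r=2 nbits=2048 chiral: 18 non-zero bits, total 30
```

The 11 heavy atoms generate 33 environments, of which 3 are structural
duplicates inside the molecule, leaving a count total of 30 spread over
18 distinct bit positions.  The molecular signature has one member per
heavy atom:

```r
molecular_signature(mol)
#> <mol_sig r=2> 11 members
#>   2x [CH2:1][CH2][CH2][CH2][CH2]|0-1(1),0-2(1),1-3(1),2-4(1)
#>   1x [CH1:1][CH2][CH2][CH2][CH3][OH1]|0-1(1),0-2(1),0-4(1),1-3(1),2-5(1)
#>   ...
```

Inverting the fingerprint against an alphabet built from the molecule
itself (18 partition equations over 10 candidate tuples, four orbits,
three PE solutions, one CE/GE survivor):

```r
alphabet <- build_alphabet(list(mol))
res <- invert_ecfp(fp, alphabet)
vapply(res$flat_molecules, canonicalize, "")
#> [1] "CC(CO)CCCCCCO"
vapply(res$stereo_molecules, canonicalize, "")
#> [1] "C[C@@H](CO)CCCCCCO" "C[C@H](CO)CCCCCCO"
vapply(res$matched, canonicalize, "")
#> [1] "C[C@H](CO)CCCCCCO"
```

One flat skeleton, two stereoisomers, and exactly one of them matches the
chirality-aware query fingerprint — the input molecule.

## Command line

A thin launcher is installed at `inst/cli/sigenum`:

```sh
sigenum fixtures make --n 200 --seed 7 --out fixtures.smi
sigenum alphabet build --smiles fixtures.smi --out alphabet.jsonl
sigenum invert --smiles fixtures.smi --alphabet alphabet.jsonl --out results.jsonl
sigenum enumerate --fp "1 71 80 80 80 80 80 80 80 222 222 ..." \
    --alphabet alphabet.jsonl --out out.jsonl
```

Identical invocations with identical seeds produce byte-identical output
files.

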