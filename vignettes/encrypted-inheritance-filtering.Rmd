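---
title: "Encrypted inheritance-model variant filtering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encrypted inheritance-model variant filtering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptMendel)
```

# The problem

Rare-disease gene discovery hinges on filtering a family's variants by a
Mendelian inheritance pattern: a recessive candidate is homozygous in the
proband while both parents are heterozygous carriers; a dominant candidate
is heterozygous in the affected individuals; a de novo candidate is a
variant of the same genotype class shared by all affected family members and
absent from all unaffected ones.  When the genotypes sit at different
hospitals, privacy law prevents pooling them in the clear.  cryptMendel
implements the filtering step as arithmetic circuits over encrypted data:
genotypes are encrypted once, a cloud evaluates the filter homomorphically,
and only a committee-authorized decryption reveals the result — either a
bare count of matching variants or a shuffled vector whose zeros mark them.

# Genotype representation

Each diploid GT call is encoded as two bits, one per *allelic channel*:

| GT        | (first, second) | meaning                          |
|-----------|-----------------|----------------------------------|
| `0/0`, `./.` | (0, 0)       | homozygous reference / no call   |
| `x/0`, `0/x` | (0, 1)       | heterozygous non-reference       |
| `x/x`     | (1, 0)          | homozygous non-reference         |

The code (1,1) is unrepresentable, and the two channels let one equality
test per channel express "is this sample's genotype exactly the queried
class".  Two conventions are not fixed by the table and are decided here:
genotypes with two *distinct* non-reference alleles (`1/2`) sit on both
chromosomes and encode as homozygous (1,0); half-missing calls (`./1`) have
one confirmed non-reference allele and encode as heterozygous (0,1).  Both
are flagged by `encodeGenotype()` so an analyst can audit them.  Phased
`|` separators are equivalent to `/` — the code is unordered by
construction.

The channel matrices (variants × samples) are partitioned row-wise into
SIMD blocks of `slotCount` slots.  The final block is zero-padded and a
plaintext validity mask records which slots are real; correctness is
restored inside the circuits (below) rather than by a special pad genotype.

# The circuits

All arithmetic is slotwise modulo a prime plaintext modulus $t$.  For one
sample $i$ with encrypted channel value $V[i]$ and replicated encrypted
query bit $Q[i]$, the equality indicator is

$$ R_s[i] \;=\; 1 + (V[i]-Q[i])\,(Q[i]-V[i]), $$

which is 1 iff $V[i]=Q[i]$ for bit inputs (1 multiplication, 2
subtractions, 1 addition).

**MUL-IN (recessive/dominant).**  Indicators are combined by cumulative
multiplication across samples within each channel, the two channel
products are multiplied, padded slots are zeroed by a plaintext mask
multiplication, per-block results are added, and a rotate-and-add total sum
leaves the encrypted *count* of matching variants in every slot.  Per
block of $s$ samples this costs $4s-1$ ciphertext multiplications and $6s$
additions, plus $v-1$ scalar slot additions for the final total over $v$
variants.  The researcher learns only the count.

**ADD-IN (recessive/dominant).**  The same indicators are instead summed
across samples and channels and the encrypted constant $2s$ is subtracted —
one indicator per sample per channel, so a full match leaves exactly 0.
(The natural "subtract the sample count $s$" reading is inconsistent with
the two-channel indicator sum, whose full-match value is $2s$; subtracting
$2s$ is the choice that makes the zero-residual contract hold.)  A
plaintext correction adds $2s+1$ on padded slots only, guaranteeing they
are nonzero for every query pattern.  Each block is then multiplied by an
encrypted slotwise mask drawn uniformly from $[1, t-1]$ and the blocks are
shuffled.  Cost per block: $2s+1$ multiplications (including the mask) and
$8s$ additions.  Decryption shows zeros at matches and uniform nonzero
values elsewhere, in permuted order.

**De novo.**  Per channel, the MUL-IN variant multiplies the affected
samples' values (presence in all affected) and the terms $1-V$ over
unaffected samples (absence in all unaffected), multiplies the two
products, adds the channels and sums as above: $2a+2u-2$ multiplications
and $2u+1$ additions per block, plus $v-1$ slot additions.  The ADD-IN
variant forms per-channel residuals $\sum_a V + \sum_u (1-V) - (a+u)$,
multiplies the two channel residuals (zero iff either channel passes) and
masks/shuffles: exactly **2** multiplications per block regardless of
cohort size, and $2a+4u$ additions.  Exactness of the zero test requires
$t > (a+u)^2$, which the engine enforces.

A characterization worth knowing: the de novo algebra tests each genotype
class per channel independently, so a variant homozygous in all affected
samples passes the homozygous channel even if an unaffected relative is
heterozygous.  This is the circuit's defined semantics; the test suite
pins it down explicitly.

# Depth accounting and the backend contract

Every ciphertext carries its accumulated multiplicative depth; exceeding
the budget raises the same noise-exhaustion error a real leveled scheme
produces.  Multiplication sets `max(depths) + 1`; addition and subtraction
keep `max(depths)`; the plaintext mask multiplication is also charged one
level (conservative accounting for a leveled scheme).  Cumulative
multiplication uses a balanced binary tree, so its depth contribution is
$\lceil \log_2 k \rceil$ rather than $k-1$: at 256 samples the MUL-IN
recessive/dominant circuit consumes $1 + 8 + 1 + 1 = 11$ levels, inside a
budget of 12, while both ADD-IN circuits consume exactly 2 for any cohort
size.  These are the two depth budgets the default parameters encode.

The mock backend stores the slot vector itself as the payload and applies
true mod-$t$ semantics, so every circuit is verifiable bit-exactly against
a direct modular evaluation; the test suite does exactly that on random
straight-line circuits, and checks the depth tracker against an
independent DAG-depth computation.  A real BFV adapter would implement the
same generics (`heEncrypt`, `heMul`, ...) against lattice ciphertexts; the
operation tallies at vector granularity are backend-independent.

Instrumentation keeps two addition counters on purpose: ciphertext-vector
additions, and scalar slot additions attributed to the total-sum — the two
granularities the complexity formulas mix.  Plaintext-operand operations
are tallied separately and never count toward the ciphertext columns.

# Parameters

* `t` (plaintext modulus, prime): all arithmetic wraps mod `t`, so `t`
  must exceed the variant count (counts), twice the sample count (r/d
  residuals) and $(a+u)^2$ (de novo residual products).  Default
  16 777 259, the smallest prime above $2^{24}$ — room for millions of
  variants.  The mock backend additionally caps `t` at $2^{26}$ so residue
  products stay below $2^{53}$ and double-precision arithmetic is exact.
* `depthBudget`: 2 suffices for ADD-IN, 12 for MUL-IN up to 256 samples.
* `slotCount`: SIMD slots per ciphertext (power of two; default 1024).
  Purely a throughput/ciphertext-size tradeoff; results are identical for
  any value.
* Committee: `n` members with quorum `q`.  Additive $n$-of-$n$ sharing and
  Shamir $t$-of-$n$ sharing over the plaintext ring are both implemented;
  "auto" picks additive when `q == n`.  Partial decryptions are blinded by
  a per-ciphertext pseudorandom ring vector times the member's share, and
  the shares encode the zero element, so any quorum cancels the blinding
  exactly while smaller sets see ring-uniform residue.

# The synthetic generator

`generateCohort()`/`generateCohortVcf()` emulate the shape of a
rare-variant-filtered multi-sample exome VCF: GT-only FORMAT, synthetic
coordinates (chr1–chr22 round-robin, increasing positions, random REF/ALT),
background genotype codes drawn i.i.d. per call as
(hom-ref, het, hom-alt) = (0.90, 0.08, 0.02) — a plausible post-frequency-
filter profile — and `nImplanted` rows matching the model pattern exactly.
Background rows that match by accident are redrawn, so the ground truth is
exact by construction and never depends on the background distribution.
Generation is byte-deterministic given the specification.

What it does *not* emulate: linkage disequilibrium, realistic allele
frequencies, genotyping error, multi-allelic records, annotation columns.
Passing tests therefore demonstrate circuit correctness on arbitrary
genotype configurations (the rejection/implant mechanism explores the full
code space), not population realism.  Real VCFs enter through the same
`readVcfGenotypes()` path, so the distinction does not affect the
encrypted pipeline itself.

# Numerical and degenerate-input choices

* All randomness (key material, masks, permutations, synthetic data) flows
  from explicit seeds; runs are reproducible bit-exactly and the manifest
  records every seed.
* Singleton cohorts are legal: cumulative operations over one ciphertext
  are the identity with zero cost; de novo with $u=0$ skips the unaffected
  term entirely (keeping the $2a+2u-2$ and $2a+4u$ formulas exact at
  $u=0$).
* An empty VCF yields zero blocks and a zero count.
* The output shuffle is a block permutation plus an independent cyclic
  slot rotation per block, with the permutation discarded.  A uniform
  permutation over all slots is not attempted homomorphically; the
  achieved unlinkability is "position hidden up to this permutation
  family", which combined with slotwise uniform masking leaves the
  nonzero part of the output carrying no genotype information.
* Decoding checks integrity: MUL-IN slots must all agree after the total
  sum; ADD-IN zero counts cannot exceed the number of real variants
  (padded slots are nonzero by construction).

# Problem sizes used in the checks

The test suite and the acceptance script run at desk scale by choice:
operation-count and depth checks use 64-variant single-block cohorts and
sample counts up to 256; oracle-equivalence checks run 50 random cohorts
per model at up to ~400 variants and 7 samples; the masking-uniformity
check draws 12 800 masked residuals.  Counts and depths are structural
quantities — they do not change with the variant count beyond the explicit
$v$ terms — so these sizes exercise the same formulas that govern
million-variant runs.

# Known limitations

* The real-lattice backend is an adapter seam, not included; all shipped
  computation runs on the exact mock backend.
* No compound-heterozygote, X-linked or imprinting models.
* No multi-allelic decomposition or variant normalization; records are
  taken verbatim.
* The committee protocol models transport as function calls passing
  serializable messages (honest-but-curious parties, no verifiable DKG,
  no key rotation).
* Timings reported in manifests are informational only; nothing in the
  package asserts wall-clock performance.
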