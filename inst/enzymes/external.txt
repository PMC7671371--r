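# provenance: external (PeptideCutter-published definitions).
# These enzymes reproduce the specificity tables of the ExPASy
# PeptideCutter service; they are shipped for convenience and are not part
# of the package's oracle-tested core.

NAME: asp-n-pepc
# PeptideCutter's stricter asp-n: before d only
RULE: (,d)

NAME: enterokinase-pepc
# PeptideCutter ignores P5 and beyond
RULE: (d or e)(d or e)(d or e)(k,)

NAME: tev-pepc
# PeptideCutter ignores P5 and beyond
RULE: (y)()(q,)(g or s)

NAME: clostripain
RULE: (r,)

NAME: bnps-skatole
RULE: (w,)

NAME: iodosobenzoic-acid
RULE: (w,)

NAME: cnbr
RULE: (m,)

NAME: formic-acid
RULE: (d,)

NAME: glutamyl
# glutamyl endopeptidase (Glu-C): after e
RULE: (e,)

NAME: asp-n-glu-n
# combined asp-n (before d) and glu-c (after e) specificity
RULE: (,d)
RULE: (e,)

NAME: ntcb
# 2-nitro-5-thiocyanobenzoic acid: before c
RULE: (,c)

NAME: proteinase-k
RULE: (a or e or f or i or l or t or v or w or y,)

NAME: neutrophil-elastase
RULE: (a or v,)

NAME: thermolysin
RULE: (,a or f or i or l or m or v)
EXCEPTION: (d or e)(,a or f or i or l or m or v)
EXCEPTION: (,a or f or i or l or m or v)(p)

NAME: proline-endopeptidase
RULE: (h or k or r)(p,)
EXCEPTION: (h or k or r)(p,)(p)

NAME: factor-xa
RULE: (a or f or g or i or l or t or v or m)(d or e)(g)(r,)

NAME: granzyme-b
RULE: (i)(e)(p)(d,)

NAME: thrombin
RULE: (g)(r,)(g)
RULE: (a or f or g or i or l or t or v or m)(a or f or g or i or l or t or v or w or a)(p)(r,)
EXCEPTION: (a or f or g or i or l or t or v or m)(a or f or g or i or l or t or v or w or a)(p)(r,)(d or e)
EXCEPTION: (a or f or g or i or l or t or v or m)(a or f or g or i or l or t or v or w or a)(p)(r,)()(d or e)

NAME: caspase-1
RULE: (f or w or y or l)()(h or a or t)(d,)
EXCEPTION: (d,)(p or e or d or q or k or r)

NAME: caspase-2
RULE: (d)(v)(a)(d,)
EXCEPTION: (d,)(p or e or d or q or k or r)

NAME: caspase-3
RULE: (d)(m)(q)(d,)
EXCEPTION: (d,)(p or e or d or q or k or r)

NAME: caspase-4
RULE: (l)(e)(v)(d,)
EXCEPTION: (d,)(p or e or d or q or k or r)

NAME: caspase-5
RULE: (l or w)(e)(h)(d,)

NAME: caspase-6
RULE: (v)(e)(h or i)(d,)
EXCEPTION: (d,)(p or e or d or q or k or r)

NAME: caspase-7
RULE: (d)(e)(v)(d,)
EXCEPTION: (d,)(p or e or d or q or k or r)

NAME: caspase-8
RULE: (i or l)(e)(t)(d,)
EXCEPTION: (d,)(p or e or d or q or k or r)

NAME: caspase-9
RULE: (l)(e)(h)(d,)

NAME: caspase-10
RULE: (i)(e)(a)(d,)
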