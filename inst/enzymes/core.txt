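# Proteases with fully specified cleavage rules.

NAME: trypsin
# cleaves after k or r; p in P1' blocks, except in the w-k-p and m-r-p
# contexts; some P2/P1' pairs considerably block the action
RULE: (k or r,)
RULE: (w)(k,)(p)
RULE: (m)(r,)(p)
EXCEPTION: (k or r,)(p)
EXCEPTION: (d)(k,)(d)
EXCEPTION: (c)(k,)(d or h or y)
EXCEPTION: (r)(r,)(h or r)
EXCEPTION: (c)(r,)(k)

NAME: staphylococcal-peptidase-i
# cleaves after e unless preceded by another e
RULE: (e,)
EXCEPTION: (e)(e,)

NAME: hydroxylamine
# cleaves between n and g
RULE: (n,)(g)

NAME: thrombin-sg
# sequencing-grade thrombin: cleaves only on the full motif lvpr|gs
RULE: (l)(v)(p)(r,)(g)(s)

NAME: chymotrypsin-high
# high specificity: after f, y or w, not before p; w additionally not
# before m
RULE: (f or y or w,)
EXCEPTION: (f or y or w,)(p)
EXCEPTION: (w,)(m)

NAME: bromelain
RULE: (k or a or y,)

NAME: pepsin-simplified
# simplified pepsin (pH > 2): cleaves before and after f, l, w or y; the
# real enzyme carries many further exceptions
RULE: (,f or l or w or y,)

NAME: enterokinase
# full-length recognition: four acidic positions then k
RULE: (d or e)(d or e)(d or e)(d or e)(k,)

NAME: tev
# tobacco etch virus protease, full seven-position recognition
RULE: (e)()()(y)()(q,)(g or s)

NAME: asp-n
# asp-n endopeptidase: cleaves before d or c
RULE: (,d or c)

NAME: lys-c
RULE: (k,)

NAME: lys-n
RULE: (,k)

NAME: arg-c
RULE: (r,)
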