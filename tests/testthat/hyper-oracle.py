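"""Exact hypergeometric upper-tail probabilities with big-integer binomials.

For every G in 1..Gmax, n in 0..G, K in 0..G and every attainable count
a in [max(0, n+K-G), min(n, K)], prints P(X >= a) for
X ~ Hypergeometric(K, G-K, n), one value per line, computed as an exact
integer ratio (Python integers are arbitrary precision; the final division
of two integers is correctly rounded). Row order matches the grid the R
test generates.
"""
import sys
from math import comb

gmax = int(sys.argv[1]) if len(sys.argv) > 1 else 60
out = []
for G in range(1, gmax + 1):
    for n in range(G + 1):
        for K in range(G + 1):
            lo = max(0, n + K - G)
            hi = min(n, K)
            den = comb(G, n)
            # tail sums from the top so each prefix is exact
            terms = [comb(K, k) * comb(G - K, n - k) for k in range(lo, hi + 1)]
            tail = 0
            tails = [0] * len(terms)
            for i in range(len(terms) - 1, -1, -1):
                tail += terms[i]
                tails[i] = tail
            out.extend(t / den for t in tails)
sys.stdout.write("\n".join(repr(v) for v in out))
sys.stdout.write("\n")
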