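# Top diseases co-mentioned with a compound, by co-occurrence score.
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX sio: <http://semanticscience.org/resource/>
PREFIX compound: <http://rdf.ncbi.nlm.nih.gov/pubchem/compound/>
SELECT ?neighbor ?score
WHERE {
  ?cooc rdf:type sio:SIO_000993 ;
        rdf:subject compound:CID{{cid}} ;
        rdf:object ?neighbor ;
        sio:SIO_000300 ?score .
}
ORDER BY DESC(?score) ASC(STR(?neighbor))
LIMIT {{limit}}
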