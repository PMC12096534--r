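# Diseases associated with the gene most co-mentioned with a compound.
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX sio: <http://semanticscience.org/resource/>
PREFIX compound: <http://rdf.ncbi.nlm.nih.gov/pubchem/compound/>
SELECT ?disease ?score
WHERE {
  {
    SELECT ?gene
    WHERE {
      ?cg rdf:type sio:SIO_001257 ;
          rdf:subject compound:CID{{cid}} ;
          rdf:object ?gene ;
          sio:SIO_000300 ?cgscore .
    }
    ORDER BY DESC(?cgscore) ASC(STR(?gene))
    LIMIT 1
  }
  ?gd rdf:type sio:SIO_000983 ;
      rdf:subject ?gene ;
      rdf:object ?disease ;
      sio:SIO_000300 ?score .
}
ORDER BY DESC(?score) ASC(STR(?disease))
LIMIT {{limit}}
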