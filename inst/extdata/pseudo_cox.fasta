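>pseudo_cox
IHSRRMQIYYDKVATKLMHWWSCIAPHWDQQHKISAGDIVNHILQFMAANEDWSNLSLID
VGWNDDWVCEPAQEEMSECWAQSVKTIFMRVCDTCVTQGREVSKRNGRGQFEQKPPRQWT
FIHTHPNCATPYNIVTPPCSQHVTCDKYCDSDYHEDDLMYRPQQRPSLNVWLVSQRVVKE
CDAGKRGIPKYVATHHDCNLRIYEFGSNVCMYCPWMMWQLREKLDDGLNDHYFWYVFEWC
DSNTQADTIRLCPGLSFSRNMRCDYTRLCHHRVLEDALIMCKCYKAKVHLGRTQHENHPD
DWQLFLVHECYNDHHFQENAQDGDIWAREMPCSACQAKVQMLIDLPNLLARSRVIKVGMV
MRYVNLCHNTYACIQLPIRVMRHYMIQPATVCFDFHTPIRKEYYRFKRQGQSSWEPQMHD
WDLQRHKIAEKGVVFRVAKAYQIFHKNLRAMFRAMWCCILSQRFLFHEMFAFWPDASDKT
AFIWQYGFHYTTFNPMDTASFYVAHCWTMKRTEMVFRWQGQRSYSLSGFIVQTWHHGTAK
DTKKDFIFRTQEKSYKQNTKSFGGMMRQVAAQNCNWYSDLVLQLRKGWSEHCHSKPDCFI
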