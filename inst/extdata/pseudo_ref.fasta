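>pseudo_ref
AGPRNESFNCWRQTNLVCFNFSDNDDLEIVCPKNFKPVKSHVFFMETIKDRYKGERANGP
EIGSGTHATYGFTDYRTIEPANDWPAGVYVAYLCEFRATKPNWVNKDCTCLPLQGWNNCE
CGRTNEEDMSGGAEWPDFGWRLGMWEVSVEWGNAFGEQPCVSQVRITMLSHPPINRRLIL
ISAYFLMAVDDCPNHPRAQEDSHFKGVMWEKPWICCNFDYNYWNYLAQSGRKKKDVMTDF
CCAMGGKADHIQHYNLKSMKVVIECVRIAPSYHTTPALHQVERFTLPNRTQVMCPYCLWT
KMSCQPYNSMRIRYGLIINRNWYPGWIVPHIFVEGKYAPPNIVCIPVERHDGYPIPYKKL
LDPVAKKTFSSCECNHVCGSSVVWSKCNEQTMAKACEWWILRYMWVHTVTPAPLFCIPRK
GYIHFFIGELSYRQEQTEEQMLTEAFVYGMLYNTQHPRWIACNGPMKVFTPVHQWMENLK
YERNTESSGFVCRWQSRWTYSNFKSPQFPDYLVVKSLPSVIKGTGDQFKMQQEVATCSDW
TPTYSVLGWQYWYIPQRRFELYMEVTEIWEANPNFRNGQTGMFLTHDIHSRFERIQCIKI
IPIVWQDDSHMYLMAVISTSPTKYKGCQENRDMEWHHVLTPMYKQTTHAIEEHIVAMMLC
VYWREAPWPGNLHETEPMAADELRQKYLAFQAHENDHGMKPHESDVVWRICSWTCMKGVS
LHPHKSKPFETTTNMTWLLAKNAVTALLYLSNGEEIHRVRIHRLLVHEPHYPHNPWTMLG
HIHNIGDKPEDNQYWMCKCYRDDIMSDYDCAQTNSLVFDAWKAWKFTWCHSHLNYIILQP
QRMFPYCYEHAAVNCMFAPWAMAKNEKKQMRSVYAKMYRCDRWMKSKMGNAQYSYLYQKF
GVWVCKTPPETPIVQTDEELQHHMEVEFPELDFQWWCNSGSYHQGINDLDQGVKGPCRDP
MWSMVDLVGRPQHMSKEMRPNYCNINFNKNMRCLHMPCAINAENTTKLYCWDNMMTDMDQ
SAIRVQQNEWQAWSDGKRDTRSFATEQPQLIWWCFTHWCDPNGTAI
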