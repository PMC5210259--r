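<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="bedSchema">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="field" minOccurs="4" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="name" type="xs:string" use="required"/>
            <xs:attribute name="type" use="required">
              <xs:simpleType>
                <xs:restriction base="xs:string">
                  <xs:enumeration value="string"/>
                  <xs:enumeration value="integer"/>
                  <xs:enumeration value="float"/>
                  <xs:enumeration value="char"/>
                </xs:restriction>
              </xs:simpleType>
            </xs:attribute>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="experimentType" use="required">
        <xs:simpleType>
          <xs:restriction base="xs:string">
            <xs:enumeration value="cnv"/>
            <xs:enumeration value="dnamethylation"/>
            <xs:enumeration value="dnaseq"/>
            <xs:enumeration value="mirnaseq"/>
            <xs:enumeration value="rnaseq"/>
            <xs:enumeration value="rnaseqv2"/>
          </xs:restriction>
        </xs:simpleType>
      </xs:attribute>
      <xs:attribute name="subtype" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
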